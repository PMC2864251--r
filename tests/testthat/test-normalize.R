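make_cm <- function(values, labels = c("brain.BN-Lx.1", "liver.BN-Lx.1")) {
  m <- matrix(values, ncol = length(labels),
              dimnames = list(sprintf("mir-%02d", seq_len(length(values) /
                                                            length(labels))),
                              labels))
  count_matrix(m)
}

test_that("ocm is the mean after dropping the three highest rows", {
  # uniform column: ocm = c, all normalized values 1
  m <- make_cm(rep(10, 12), labels = c("brain.BN-Lx.1", "liver.BN-Lx.1"))
  norm <- ocm_normalize(m)
  expect_equal(unname(ocm_values(norm)), c(10, 10))
  expect_true(all(norm == 1))
  # worked example: drop {100, 50, one 10}; ocm = mean of four 10s = 10
  m2 <- count_matrix(matrix(c(100, 50, 10, 10, 10, 10, 10), ncol = 1,
                            dimnames = list(sprintf("r%d", 1:7),
                                            "brain.BN-Lx.1")))
  n2 <- ocm_normalize(m2)
  expect_equal(unname(ocm_values(n2)), 10)
  expect_equal(as.numeric(n2), c(100, 50, 10, 10, 10, 10, 10) / 10)
  expect_setequal(attr(n2, "removed_rows")[[1]], c("r1", "r2", "r3"))
})

test_that("ties at the third-highest count break lexicographically", {
  m <- count_matrix(matrix(c(9, 5, 5, 5, 1), ncol = 1,
                           dimnames = list(c("zz", "bb", "aa", "cc", "dd"),
                                           "brain.BN-Lx.1")))
  n <- ocm_normalize(m)
  expect_identical(attr(n, "removed_rows")[[1]], c("zz", "aa", "bb"))
  expect_equal(unname(ocm_values(n)), mean(c(5, 1)))
})

test_that("normalization refuses columns with too few nonzero rows", {
  m <- count_matrix(matrix(c(5, 3, 1, 0, 0), ncol = 1,
                           dimnames = list(sprintf("r%d", 1:5),
                                           "brain.BN-Lx.1")))
  expect_error(ocm_normalize(m), "<= 3 nonzero")
})

test_that("normalization is scale-equivariant per column", {
  for (s in 1:5) {
    sim <- simulate_counts(s, n_mirnas = 40)
    norm1 <- ocm_normalize(sim$counts)
    scaled <- unclass(sim$counts)
    scaled[, 3] <- scaled[, 3] * 7
    norm2 <- ocm_normalize(count_matrix(scaled))
    expect_equal(unclass(norm1), unclass(norm2), ignore_attr = TRUE)
  }
})

test_that("a dominant liver-like row is among the removed rows", {
  sim <- simulate_counts(7, n_mirnas = 100)
  raw <- unclass(sim$counts)
  raw["mir-001", "liver.BN-Lx.1"] <- ceiling(0.3 * sum(raw[, "liver.BN-Lx.1"]) / 0.7)
  m <- count_matrix(raw)
  expect_gt(raw["mir-001", "liver.BN-Lx.1"] / sum(raw[, "liver.BN-Lx.1"]), 0.2)
  norm <- ocm_normalize(m)
  expect_true("mir-001" %in% attr(norm, "removed_rows")[["liver.BN-Lx.1"]])
})

# --- specificity and avoidance ---

# six tissues x two strains, one replicate each; row values given per tissue
# (equal in both strains unless strain2 is supplied)
spec_matrix <- function(focal_row, strain1, strain2 = strain1,
                        n_background = 30, base = 200) {
  tissues <- c("brain", "liver", "spleen", "heart", "testis", "kidney")
  strains <- c("BN-Lx", "SHR")
  labels <- as.vector(outer(tissues, strains,
                            function(t, s) paste(t, s, "1", sep = ".")))
  m <- matrix(base, nrow = n_background + 1, ncol = length(labels),
              dimnames = list(c(focal_row,
                                sprintf("bg-%02d", seq_len(n_background))),
                              labels))
  for (i in seq_along(tissues)) {
    m[focal_row, paste(tissues[i], "BN-Lx", "1", sep = ".")] <- strain1[i]
    m[focal_row, paste(tissues[i], "SHR", "1", sep = ".")] <- strain2[i]
  }
  count_matrix(m)
}

test_that("tissue-specific calls require >= fold in every strain, inclusively", {
  # uniform row: no call
  norm <- ocm_normalize(spec_matrix("mir-u", rep(200, 6)))
  expect_identical(nrow(call_specific(norm)), 0L)
  # exactly 5.0x in both strains: called (threshold inclusive)
  norm5 <- ocm_normalize(spec_matrix("mir-s", c(1000, rep(200, 5))))
  calls <- call_specific(norm5)
  expect_identical(calls$row, "mir-s")
  expect_identical(calls$tissue, "brain")
  # 6x in one strain but 4x in the other: no call
  norm64 <- ocm_normalize(spec_matrix("mir-s", c(1200, rep(200, 5)),
                                      c(800, rep(200, 5))))
  expect_identical(nrow(call_specific(norm64)), 0L)
})

test_that("avoidant calls mirror the rule with the epsilon floor", {
  # zero in brain, comfortably expressed elsewhere, both strains
  norm <- ocm_normalize(spec_matrix("mir-a", c(0, rep(200, 5))))
  calls <- call_avoidant(norm)
  expect_identical(calls$row, "mir-a")
  expect_identical(calls$tissue, "brain")
  # 5x lower in one strain only: no call
  norm1 <- ocm_normalize(spec_matrix("mir-a", c(40, rep(200, 5)),
                                     rep(200, 6)))
  expect_identical(nrow(call_avoidant(norm1)), 0L)
  # uniform: no call
  normu <- ocm_normalize(spec_matrix("mir-a", rep(200, 6)))
  expect_identical(nrow(call_avoidant(normu)), 0L)
})

test_that("specific and avoidant are mutually exclusive per (row, tissue)", {
  for (s in 1:5) {
    sim <- simulate_counts(s, n_mirnas = 50)
    norm <- ocm_normalize(sim$counts)
    sp <- call_specific(norm)
    av <- call_avoidant(norm)
    expect_identical(nrow(merge(sp[c("row", "tissue")],
                                av[c("row", "tissue")])), 0L)
  }
})

test_that("the fold rule agrees exactly with a brute-force oracle", {
  for (s in 1:4) {
    sim <- simulate_counts(
      s, n_mirnas = 50,
      planted_specific = data.frame(row = c("mir-003", "mir-007"),
                                    tissue = c("brain", "testis"),
                                    fold = c(8, 10)))
    norm <- ocm_normalize(sim$counts)
    for (dir in c("specific", "avoidant")) {
      got <- if (dir == "specific") call_specific(norm) else call_avoidant(norm)
      want <- oracle_specificity(unclass(sim$counts), 5, dir)
      got <- got[order(got$row, got$tissue), c("row", "tissue")]
      want <- want[order(want$row, want$tissue), ]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("planted 8-fold rows are recovered and 2-3-fold rows never called", {
  sim <- simulate_counts(
    21, n_mirnas = 100,
    planted_specific = data.frame(row = c("mir-010", "mir-020", "mir-030"),
                                  tissue = c("brain", "testis", "liver"),
                                  fold = c(8, 8, 8)))
  calls <- call_specific(ocm_normalize(sim$counts))
  for (i in 1:3)
    expect_true(any(calls$row == sim$truth$specific$row[i] &
                      calls$tissue == sim$truth$specific$tissue[i]))
  sim_lo <- simulate_counts(
    22, n_mirnas = 100,
    planted_specific = data.frame(row = c("mir-010", "mir-020"),
                                  tissue = c("brain", "testis"),
                                  fold = c(2, 3)))
  expect_identical(nrow(call_specific(ocm_normalize(sim_lo$counts))), 0L)
})

# --- correlations and clustering ---

test_that("sample correlations behave at the boundaries", {
  sim <- simulate_counts(3, n_mirnas = 60)
  norm <- ocm_normalize(sim$counts)
  rho <- sample_correlation(norm)
  expect_equal(unname(diag(rho)), rep(1, ncol(norm)))
  expect_equal(rho, t(rho))
  # a rank-reversing pair has rho = -1
  m <- count_matrix(matrix(c(1:8, 8:1), ncol = 2,
                           dimnames = list(sprintf("r%d", 1:8),
                                           c("brain.BN-Lx.1", "brain.SHR.1"))))
  expect_equal(sample_correlation(ocm_normalize(m))[1, 2], -1)
})

test_that("same-tissue strain pairs correlate higher than cross-tissue pairs", {
  sim <- simulate_counts(
    4, n_mirnas = 200,
    planted_specific = data.frame(row = sprintf("mir-%03d", 1:30),
                                  tissue = rep(c("brain", "testis", "liver"),
                                               each = 10),
                                  fold = 8))
  norm <- ocm_normalize(sim$counts)
  rho <- sample_correlation(norm)
  same <- rho["brain.BN-Lx.1", "brain.SHR.1"]
  cross <- rho["brain.BN-Lx.1", "testis.SHR.1"]
  expect_gt(same, cross)
})

test_that("miRNA trees merge identical rows first and have n-1 merges", {
  tissues <- c("brain.BN-Lx.1", "liver.BN-Lx.1")
  m <- count_matrix(matrix(c(50, 50, 400, 10, 10,
                             50, 50, 10, 400, 10), ncol = 2,
                           dimnames = list(c("dup1", "dup2", "far1", "far2",
                                             "mid"), tissues)))
  tr <- mirna_tree(ocm_normalize(m))
  expect_identical(nrow(tr$hclust$merge), 4L)
  first <- tr$hclust$merge[1, ]
  expect_setequal(tr$hclust$labels[-first], c("dup1", "dup2"))
  # rows with pairwise distances (tiny, large, large): close pair first
  tr3 <- mirna_tree(ocm_normalize(count_matrix(
    matrix(c(100, 101, 4000, 1, 7, 30,
             100, 101, 4100, 1, 9, 25), ncol = 2,
           dimnames = list(c("a", "b", "c", "d", "e", "f"), tissues)))))
  first3 <- tr3$hclust$merge[1, ]
  expect_setequal(tr3$hclust$labels[-first3], c("a", "b"))
})
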