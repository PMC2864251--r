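mk_reads <- function(p5, strand = "+", chrom = "chrS", len = 27L) {
  strand <- rep_len(strand, length(p5))
  start <- ifelse(strand == "+", p5, p5 - len + 1L)
  aligned_reads(read_id = sprintf("r%05d", seq_along(p5)), chrom = chrom,
                start = start, end = start + len,
                strand = rep_len(strand, length(p5)))
}

test_that("structural-annotation filtering removes overlapping reads", {
  ann <- annotation_set(
    chrom = "chrS", start = c(1000, 5000, 9000, 13000),
    end = c(2000, 6000, 10000, 14000), strand = "+",
    class = c("rRNA", "gene", "snoRNA", "scRNA"),
    name = c("rrna1", "gene1", "sno1", "sc1"))
  p5 <- c(1500, 5500, 9500, 13500, 3000, 4000, 7000, 11000, 16000, 20000)
  r <- mk_reads(p5)
  kept <- filter_structural(r, ann)
  expect_identical(nrow(kept), 6L)
  expect_true(all(five_prime(kept) %in% c(3000, 4000, 7000, 11000, 16000,
                                          20000)))
  # strand-agnostic: an antisense read over a gene is removed too
  anti <- mk_reads(5500, strand = "-")
  expect_identical(nrow(filter_structural(anti, ann)), 0L)
})

test_that("unique_starts deduplicates 5' ends per strand", {
  r <- bind_reads(
    aligned_reads(sprintf("d%02d", 1:100), "chrS", 100, 122, "+",
                  copies = 3L),
    aligned_reads("m1", "chrS", 100, 122, "-"))
  us <- unique_starts(r)
  expect_identical(nrow(us), 2L)
  expect_identical(us$pos[us$strand == "+"], 100L)
  expect_identical(us$pos[us$strand == "-"], 121L)
  expect_identical(nrow(unique_starts(mk_reads(integer(0)))), 0L)
})

test_that("core detection requires more than 20 starts within 2 kb", {
  # 21 unique starts within 1.5 kb: one core
  s21 <- seq(10000L, 11500L, length.out = 21)
  expect_identical(nrow(detect_cores(s21)), 1L)
  # 20 starts within 500 bp: zero cores
  s20 <- seq(10000L, 10500L, length.out = 20)
  expect_identical(nrow(detect_cores(s20)), 0L)
  # 21 starts spanning 2.5 kb, no 21-subset within 2 kb: zero cores
  s_sp <- seq(10000L, 12500L, length.out = 21)
  expect_identical(nrow(detect_cores(s_sp)), 0L)
})

test_that("core detection agrees with an exhaustive window scan", {
  set.seed(5)
  for (rep in 1:5) {
    n_dense <- 40
    starts <- sort(unique(c(
      sample.int(100000, 300),
      35000L + sample.int(1500, n_dense),
      70000L + sample.int(1200, 30))))
    got <- detect_cores(starts)
    want <- oracle_detect_cores(starts)
    expect_equal(got, want)
  }
})

test_that("extension absorbs chains of nearby starts and stops at gaps", {
  params <- cluster_params()
  core_starts <- seq(10000L, 9900L + 2L * 50L * 21L, by = 50L)[1:21]
  # no starts beyond the core: cluster equals the core span
  cores <- detect_cores(core_starts, params)
  cl <- extend_cluster(cores[1, ], core_starts, params)
  expect_identical(cl$start, core_starts[1])
  expect_identical(cl$end, core_starts[21] + 1L)
  expect_identical(cl$n_unique_starts, 21L)
  # a start 900 bp past the end is absorbed; 1,200 bp further is not
  more <- c(core_starts, max(core_starts) + 900L, max(core_starts) + 2100L)
  cl2 <- extend_cluster(detect_cores(more, params)[1, ], more, params)
  expect_identical(cl2$end, max(core_starts) + 900L + 1L)
  expect_identical(cl2$n_unique_starts, 22L)
  # a chain of starts 999 bp apart is absorbed end to end
  chain <- c(core_starts, max(core_starts) + cumsum(rep(999L, 10)))
  cl3 <- extend_cluster(detect_cores(chain, params)[1, ], chain, params)
  expect_identical(cl3$n_unique_starts, 31L)
})

test_that("merging unites nearby clusters and classifies orientation", {
  params <- cluster_params()
  mk_cl <- function(start, end, strand)
    data.frame(chrom = "chrS", start = start, end = end, strand = strand,
               n_unique_starts = 30L, stringsAsFactors = FALSE)
  # abutting opposite strands, minus left: divergent
  div <- merge_adjacent(rbind(mk_cl(1000L, 5000L, "-"),
                              mk_cl(5100L, 9000L, "+")), params)
  expect_identical(nrow(div), 1L)
  expect_identical(div$orientation_class, "divergent")
  expect_identical(div$n_unique_starts, 60L)
  # plus left, minus right: convergent
  conv <- merge_adjacent(rbind(mk_cl(1000L, 5000L, "+"),
                               mk_cl(5100L, 9000L, "-")), params)
  expect_identical(conv$orientation_class, "convergent")
  # isolated cluster: single
  single <- merge_adjacent(mk_cl(1000L, 5000L, "+"), params)
  expect_identical(single$orientation_class, "single")
  # same strand, 5 kb apart: not merged
  apart <- merge_adjacent(rbind(mk_cl(1000L, 5000L, "+"),
                                mk_cl(10000L, 15000L, "+")), params)
  expect_identical(nrow(apart), 2L)
  # merging is idempotent on the merged intervals
  merged <- merge_adjacent(rbind(mk_cl(1000L, 5000L, "+"),
                                 mk_cl(5100L, 9000L, "+"),
                                 mk_cl(30000L, 34000L, "-")), params)
  again <- merge_adjacent(
    data.frame(chrom = merged$chrom, start = merged$start, end = merged$end,
               strand = "+", n_unique_starts = merged$n_unique_starts,
               stringsAsFactors = FALSE), params)
  expect_identical(again$start, merged$start)
  expect_identical(again$end, merged$end)
})

test_that("planted clusters are recovered with tight boundaries", {
  sim <- simulate_cluster_reads(3, genome_length = 5e6, k = 6)
  cl <- call_pirna_clusters(sim$reads)
  expect_identical(nrow(cl), 6L)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    ov <- pmin(cl$end, tr$end) - pmax(cl$start, tr$start)
    hit <- which(cl$strand == tr$strand &
                   ov >= 0.9 * (tr$end - tr$start) &
                   ov >= 0.9 * (cl$end - cl$start))
    expect_identical(length(hit), 1L)
  }
})

test_that("background-only read sets yield no clusters", {
  sim <- simulate_cluster_reads(4, genome_length = 1e7, k = 0)
  expect_identical(nrow(call_pirna_clusters(sim$reads)), 0L)
})

test_that("detection is symmetric under reverse-complementing the genome", {
  sim <- simulate_cluster_reads(5, genome_length = 2e6, k = 3)
  cl <- call_pirna_clusters(sim$reads)
  L <- unname(sim$chrom_lengths)
  rc <- sim$reads
  old_start <- rc$start
  rc$start <- L - rc$end
  rc$end <- L - old_start
  rc$strand <- ifelse(rc$strand == "+", "-", "+")
  cl_rc <- call_pirna_clusters(rc)
  expect_identical(nrow(cl_rc), nrow(cl))
  mirrored <- data.frame(start = L - cl_rc$end, end = L - cl_rc$start,
                         strand = ifelse(cl_rc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_identical(mirrored$start, cl$start)
  expect_identical(mirrored$end, cl$end)
  expect_identical(mirrored$strand, cl$strand)
})

test_that("divergent pair geometry is recovered after merging", {
  sim <- simulate_cluster_reads(6, genome_length = 5e6, k = 4,
                                divergent_fraction = 1)
  cl <- call_pirna_clusters(sim$reads)
  merged <- merge_adjacent(cl)
  two <- merged[merged$n_members == 2, ]
  expect_identical(nrow(two), 2L)
  expect_true(all(two$orientation_class == "divergent"))
})

test_that("cluster characteristics report planted densities", {
  expect_true(is.na(cluster_characteristics(
    NULL, chrom_lengths = c(chrS = 1e6))$gene_density_ratio))
  # one gene fully inside one cluster
  loc <- data.frame(chrom = "chrS", start = 1000L, end = 11000L)
  genes <- annotation_set("chrS", c(2000, 50000), c(3000, 52000), "+",
                          "gene", c("g_in", "g_out"))
  ch <- cluster_characteristics(loc, genes = genes,
                                chrom_lengths = c(chrS = 1e6))
  expect_identical(ch$genes_inside, 1)
  expect_identical(ch$genes_fully_inside, 1)
  # planted 2x gene enrichment recovered within 20%
  sim <- simulate_cluster_reads(8, genome_length = 2e7, k = 50,
                                cluster_length_range = c(8000, 16000),
                                gene_density_in = 8, gene_density_out = 4)
  cl <- call_pirna_clusters(sim$reads)
  ch2 <- cluster_characteristics(merge_adjacent(cl), genes = sim$genes,
                                 repeats = sim$repeats,
                                 conservation = sim$conservation,
                                 chrom_lengths = sim$chrom_lengths)
  expect_gt(ch2$gene_density_ratio, 2 * 0.8)
  expect_lt(ch2$gene_density_ratio, 2 * 1.2)
  # repeats planted depleted inside; conservation depleted inside
  expect_lt(ch2$repeat_frac_inside, ch2$repeat_frac_outside)
  expect_lt(ch2$conserved_frac_inside, ch2$conserved_frac_genome)
})
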