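# Shared fixtures: a toy two-arm miRNA locus, deterministic editing read
# mixtures, and independent brute-force oracles used across test files.

# Annotation with one precursor on each strand, each with a 5p and 3p arm.
toy_annotation <- function() {
  annotation_set(
    chrom = rep("chr1", 6),
    start = c(100, 110, 148, 500, 548, 510),
    end = c(180, 132, 170, 580, 570, 532),
    strand = c("+", "+", "+", "-", "-", "-"),
    class = c("pre_mirna", "mirna_arm", "mirna_arm",
              "pre_mirna", "mirna_arm", "mirna_arm"),
    name = c("mir-a", "mir-a-5p", "mir-a-3p",
             "mir-b", "mir-b-5p", "mir-b-3p"),
    parent = c(NA, "mir-a", "mir-a", NA, "mir-b", "mir-b"))
}

# A read lying inside a given arm of toy_annotation().
toy_read <- function(id, arm = "mir-a-5p", strand = NULL, sample = "brain.BN-Lx.1",
                     copies = 1L, mismatches = NULL, ann = toy_annotation()) {
  a <- ann[ann$name == arm, ]
  st <- if (is.null(strand)) a$strand else strand
  aligned_reads(read_id = id, chrom = a$chrom, start = a$start, end = a$end,
                strand = st, sequence = strrep("A", a$end - a$start),
                copies = copies, mismatches = mismatches, sample = sample)
}

# Deterministic editing mixture: n_edited reads with a single A->G at
# precursor offset `position`, n_consensus perfect reads, over one locus.
editing_mixture <- function(n_edited, n_consensus, position = 15, seed = 99) {
  rate <- n_edited / (n_edited + n_consensus)
  simulate_editing_reads(seed,
                         data.frame(precursor = "mirT", position = position,
                                    rate = rate, stringsAsFactors = FALSE),
                         coverage = n_edited + n_consensus, exact = TRUE)
}

# Independent specificity oracle: direct nested loops over the 5-fold rule,
# recomputing ocm, normalization, replicate means and the pseudocount floor
# from the raw counts.
oracle_specificity <- function(raw, fold = 5, direction = "specific") {
  smp <- parse_sample_labels(colnames(raw))
  # tie-consistent removal: order by count desc then rowname
  ocm <- sapply(seq_len(ncol(raw)), function(j) {
    o <- order(-raw[, j], rownames(raw))
    mean(raw[o[-(1:3)], j])
  })
  tissues <- unique(smp$tissue); strains <- unique(smp$strain)
  calls <- list()
  for (r in rownames(raw)) for (t in tissues) {
    ok <- TRUE
    for (s in strains) {
      val <- function(tt) {
        cols <- which(smp$tissue == tt & smp$strain == s)
        mean(sapply(cols, function(j) raw[r, j] / ocm[j]))
      }
      fl <- function(tt) {
        cols <- which(smp$tissue == tt & smp$strain == s)
        e <- mean(sapply(cols, function(j) 0.5 / ocm[j]))
        max(val(tt), e)
      }
      others <- setdiff(tissues, t)
      if (direction == "specific") {
        ok <- ok && fl(t) >= fold * max(sapply(others, fl))
      } else {
        ok <- ok && fl(t) <= min(sapply(others, fl)) / fold
      }
    }
    if (ok) calls[[length(calls) + 1L]] <- data.frame(row = r, tissue = t)
  }
  if (length(calls) == 0L)
    return(data.frame(row = character(0), tissue = character(0)))
  do.call(rbind, calls)
}

# Independent O(n*w) recomputation of the sliding-window DE statistics from
# a normalized matrix, including its own step-up FDR.
oracle_window_de <- function(norm, group_a = "BN-Lx", group_b = "SHR",
                             tissue = "liver", window = 41) {
  smp <- sample_info(norm)
  ocm <- ocm_values(norm)
  keep <- smp$tissue == tissue
  smp <- smp[keep, ]
  cols_a <- smp$label[smp$strain == group_a]
  cols_b <- smp$label[smp$strain == group_b]
  mB <- rowMeans(unclass(norm)[, cols_a, drop = FALSE])
  mS <- rowMeans(unclass(norm)[, cols_b, drop = FALSE])
  sel <- !(mB == 0 & mS == 0)
  mB <- mB[sel]; mS <- mS[sel]
  eps <- 0.5 / mean(ocm[c(cols_a, cols_b)])
  A <- (mB + mS) / 2
  D <- log2(pmax(mB, eps) / pmax(mS, eps))
  o <- order(A, names(mB))
  A <- A[o]; D <- D[o]; mB <- mB[o]; mS <- mS[o]
  n <- length(D); half <- (window - 1) / 2
  Z <- p <- numeric(n)
  for (i in seq_len(n)) {
    c0 <- i
    if (c0 < half + 1) c0 <- half + 1
    if (c0 > n - half) c0 <- n - half
    w <- D[(c0 - half):(c0 + half)]
    Z[i] <- (D[i] - mean(w)) / sd(w)
    p[i] <- 1 - pnorm(abs(Z[i]))
  }
  # step-up FDR by the explicit formula
  o2 <- order(p)
  q <- numeric(n)
  q[o2] <- rev(cummin(rev(p[o2] * n / seq_len(n))))
  q <- pmin(q, 1)
  data.frame(id = names(mB), A = A, D = D, Z = Z, p = p, q = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Independent all-pairs 5'-5' overlap histogram over unique reads.
oracle_overlap_histogram <- function(reads, max_len = 30) {
  p5 <- five_prime(reads)
  key <- paste(reads$chrom, p5, reads$strand, reads$sequence)
  u <- !duplicated(key)
  counts <- setNames(numeric(max_len), seq_len(max_len))
  idx <- which(u)
  for (i in idx) for (j in idx) {
    if (reads$chrom[i] != reads$chrom[j]) next
    if (reads$strand[i] != "+" || reads$strand[j] != "-") next
    L <- p5[j] - p5[i] + 1
    if (L >= 1 && L <= max_len) counts[L] <- counts[L] + 1
  }
  counts
}

# Exhaustive core scan: for every start-anchored window, count the starts
# it contains; qualifying windows are merged into cores.
oracle_detect_cores <- function(starts, params = cluster_params()) {
  starts <- sort(unique(starts))
  qual <- list()
  for (s in starts) {
    inwin <- starts[starts >= s & starts < s + params$core_window]
    if (length(inwin) > params$core_min_starts)
      qual[[length(qual) + 1L]] <- c(s, max(inwin))
  }
  if (length(qual) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  qual <- do.call(rbind, qual)
  out <- list()
  cs <- qual[1, 1]; ce <- qual[1, 2]
  for (i in seq_len(nrow(qual))[-1]) {
    if (qual[i, 1] <= ce) ce <- max(ce, qual[i, 2])
    else { out[[length(out) + 1L]] <- c(cs, ce); cs <- qual[i, 1]; ce <- qual[i, 2] }
  }
  out[[length(out) + 1L]] <- c(cs, ce)
  out <- do.call(rbind, out)
  data.frame(start = out[, 1], end = out[, 2] + 1L)
}
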