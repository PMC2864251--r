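#' 5'-5' overlap histogram of sense/antisense read pairs
#'
#' The ping-pong piRNA amplification cycle cleaves a target transcript
#' across from position 10 of the guide piRNA, so secondary piRNAs overlap
#' their guides by exactly 10 nt at the 5' ends. For every
#' (plus-read, minus-read) pair on the same reference the overlap length is
#' (minus 5' coordinate) - (plus 5' coordinate) + 1, where a plus read's 5'
#' coordinate is its `start` and a minus read's is `end - 1`; pairs with
#' overlap in 1..`max_len` increment the histogram.
#'
#' To echo the clonality caution applied to cluster detection, pairs are
#' counted over unique (chrom, 5' position, strand, sequence) reads by
#' default, ignoring `copies`; set `weight_by_copies = TRUE` to weight each
#' pair by the product of collapsed copy numbers.
#'
#' @param reads an [aligned_reads] object (typically restricted to one
#'   repeat region).
#' @param max_len largest overlap length tracked (default 30).
#' @param weight_by_copies logical; see above.
#' @return A list of class `pingpong_profile`: `counts` (named vector over
#'   1..max_len), `control` (`NULL` until [randomized_control()] is run),
#'   `n_plus`, `n_minus`.
#' @export
overlap_histogram <- function(reads, max_len = 30, weight_by_copies = FALSE) {
  counts <- stats::setNames(numeric(max_len), seq_len(max_len))
  if (nrow(reads) == 0L)
    return(structure(list(counts = counts, control = NULL,
                          n_plus = 0L, n_minus = 0L),
                     class = "pingpong_profile"))
  p5 <- five_prime(reads)
  key <- paste(reads$chrom, p5, reads$strand, reads$sequence, sep = "\r")
  if (weight_by_copies) {
    w <- tapply(reads$copies, key, sum)
    first <- !duplicated(key)
    u <- data.frame(chrom = reads$chrom[first], p5 = p5[first],
                    strand = reads$strand[first],
                    w = as.numeric(w[key[first]]))
  } else {
    first <- !duplicated(key)
    u <- data.frame(chrom = reads$chrom[first], p5 = p5[first],
                    strand = reads$strand[first], w = 1)
  }
  n_plus <- sum(u$strand == "+"); n_minus <- sum(u$strand == "-")
  for (ch in unique(u$chrom)) {
    up <- u[u$chrom == ch & u$strand == "+", ]
    um <- u[u$chrom == ch & u$strand == "-", ]
    if (nrow(up) == 0L || nrow(um) == 0L) next
    dd <- outer(um$p5, up$p5, `-`) + 1L
    ww <- outer(um$w, up$w)
    ok <- dd >= 1L & dd <= max_len
    if (any(ok))
      counts <- counts + vapply(seq_len(max_len),
                                function(L) sum(ww[ok & dd == L]),
                                numeric(1))
  }
  structure(list(counts = counts, control = NULL,
                 n_plus = n_plus, n_minus = n_minus),
            class = "pingpong_profile")
}

#' Randomized-fragment control histogram
#'
#' Draws plus- and minus-strand fragments of fixed length with uniformly
#' random start positions in the region and computes the same 5'-5' overlap
#' histogram, mirroring the analysis on randomized 30-mers from the same
#' repeat sequence. Seeded and reproducible.
#'
#' @param region either the region sequence (character /
#'   [Biostrings::DNAString]) or its integer length in bp.
#' @param n_plus,n_minus number of fragments per strand (typically the
#'   observed per-strand read counts).
#' @param fragment_length fragment size (default 30).
#' @param seed integer RNG seed.
#' @param max_len largest overlap length tracked (default 30).
#' @return Named numeric vector of control counts over 1..max_len.
#' @export
randomized_control <- function(region, n_plus, n_minus, fragment_length = 30,
                               seed = 1L, max_len = 30) {
  L <- if (is.numeric(region)) as.integer(region) else nchar(as.character(region))
  if (L <= fragment_length) stop("region shorter than fragment length")
  with_seed(seed, {
    hi <- L - fragment_length
    sp <- if (n_plus > 0) sample.int(hi + 1L, n_plus, replace = TRUE) - 1L
          else integer(0)
    sm <- if (n_minus > 0) sample.int(hi + 1L, n_minus, replace = TRUE) - 1L
          else integer(0)
    frags <- aligned_reads(
      read_id = sprintf("ctrl%06d", seq_len(n_plus + n_minus)),
      chrom = "region",
      start = c(sp, sm), end = c(sp, sm) + fragment_length,
      strand = rep(c("+", "-"), c(n_plus, n_minus)))
    overlap_histogram(frags, max_len = max_len)$counts
  })
}

#' Nucleotide content at read positions 1 and 10
#'
#' Ping-pong piRNAs carry diagnostic bases: primary (sense) piRNAs start
#' with a 5'-terminal uracil and secondary (antisense) piRNAs carry an
#' adenine at position 10. Positions count from each read's own 5' end
#' (1-based) on the read sequence; T is reported as U.
#'
#' @param reads an [aligned_reads] object with sequences.
#' @param positions read positions to profile (default `c(1, 10)`).
#' @return Data frame with columns `strand`, `position`, `A`, `C`, `G`, `U`
#'   (frequencies summing to 1 where reads exist).
#' @export
positional_content <- function(reads, positions = c(1L, 10L)) {
  reads <- reads[!is.na(reads$sequence), , drop = FALSE]
  out <- list()
  for (st in c("+", "-")) {
    sub <- reads[reads$strand == st, , drop = FALSE]
    for (pos in positions) {
      freq <- stats::setNames(rep(NA_real_, 4), c("A", "C", "G", "U"))
      if (nrow(sub) > 0) {
        b <- substring(sub$sequence, pos, pos)
        b <- b[nzchar(b)]
        b <- chartr("T", "U", toupper(b))
        if (length(b) > 0) {
          tb <- table(factor(b, levels = c("A", "C", "G", "U")))
          freq[] <- as.numeric(tb) / sum(tb)
        }
      }
      out[[length(out) + 1L]] <-
        data.frame(strand = st, position = pos, A = freq["A"], C = freq["C"],
                   G = freq["G"], U = freq["U"], row.names = NULL,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Ping-pong enrichment z-score
#'
#' Summarizes how far the 10-nt bin of an overlap histogram stands above
#' the other overlap lengths: z = (counts[10] - mean(others)) / sd(others),
#' where "others" are the counts over 1..30 excluding 10. A flat histogram
#' gives z near 0; mechanism-generated data gives a large positive z.
#'
#' @param profile a `pingpong_profile` from [overlap_histogram()], or a
#'   plain counts vector named by overlap length.
#' @return A single numeric z-score.
#' @export
pingpong_zscore <- function(profile) {
  counts <- if (inherits(profile, "pingpong_profile")) profile$counts
            else profile
  others <- counts[names(counts) != "10"]
  s <- stats::sd(others)
  d <- counts[["10"]] - mean(others)
  if (s == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / s
}

#' Write a ping-pong profile as TSV
#' @param profile a `pingpong_profile`.
#' @param path output file.
#' @param control optional control counts from [randomized_control()].
#' @return `path`, invisibly.
#' @export
write_pingpong <- function(profile, path, control = NULL) {
  ctl <- if (!is.null(control)) control
         else if (!is.null(profile$control)) profile$control
         else rep(NA_real_, length(profile$counts))
  df <- data.frame(overlap_length = as.integer(names(profile$counts)),
                   count = as.numeric(profile$counts),
                   control_count = as.numeric(ctl))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
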