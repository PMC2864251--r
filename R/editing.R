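#' Scan miRNA reads for candidate A-to-I editing
#'
#' ADAR deaminates adenosine to inosine, which sequencers read as guanine,
#' so editing shows up as an A-to-G substitution in an otherwise perfect
#' read. A read is *edited at p* iff its mismatch list contains exactly one
#' substitution, that substitution is A-to-G in precursor-sense orientation,
#' and it sits at precursor offset p. A read is *consensus at p* iff it
#' covers p with zero mismatches. Reads with two or more mismatches, or a
#' single non-A-to-G mismatch, count toward neither. Reads antisense to the
#' precursor strand are excluded: ADAR acts on the transcript strand.
#'
#' @param reads an [aligned_reads] object with per-read `sample` labels.
#' @param ann an [annotation_set] with `mirna_arm` and `pre_mirna` features.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path providing the
#'   precursor reference sequence.
#' @param min_overlap read-to-arm overlap rule, as in [quantify()].
#' @return Data frame with one row per (site, sample): `precursor`,
#'   `position` (0-based on the precursor), `position_1based`, `triplet`
#'   (precursor-sense bases at pos-1..pos+1), `arm`, `mature_offset`
#'   (1-based on the mature arm), `sample`, `edited`, `consensus`,
#'   `fraction`, `in_seed`.
#' @export
scan_editing <- function(reads, ann, genome, min_overlap = 0.5) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  arms <- ann[ann$class == "mirna_arm", , drop = FALSE]
  pre <- ann[ann$class == "pre_mirna", , drop = FALSE]
  if (nrow(arms) == 0L) stop("annotation contains no mirna_arm features")
  asg <- assign_arms(reads, arms, min_overlap)
  asg <- asg[!asg$antisense, , drop = FALSE]
  empty <- data.frame(precursor = character(0), position = integer(0),
                      position_1based = integer(0), triplet = character(0),
                      arm = character(0), mature_offset = integer(0),
                      sample = character(0), edited = numeric(0),
                      consensus = numeric(0), fraction = numeric(0),
                      in_seed = logical(0), stringsAsFactors = FALSE)
  if (nrow(asg) == 0L) return(empty)
  arm_of_read <- asg$row
  pre_of_arm <- stats::setNames(arms$parent, arms$name)
  pre_seq <- function(p) {
    row <- pre[pre$name == p, ]
    if (nrow(row) == 0L) stop("no pre_mirna annotation for precursor ", p)
    if (!row$chrom %in% names(genome))
      stop("precursor sequence unavailable: ", p, " (chrom ", row$chrom, ")")
    s <- Biostrings::subseq(genome[[row$chrom]], row$start + 1L, row$end)
    if (row$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }
  # per-read precursor-sense coordinates
  nmm <- n_mismatches(reads)[asg$read]
  edited_idx <- which(nmm == 1L)
  # find edited reads: exactly one mismatch that is A->G in read orientation
  sites <- list()
  for (k in edited_idx) {
    i <- asg$read[k]
    mm <- reads$mismatches[[i]]
    if (!(mm$ref == "A" && mm$read == "G")) next
    arm_name <- arm_of_read[k]
    p_name <- pre_of_arm[[arm_name]]
    prow <- pre[pre$name == p_name, ]
    gpos <- if (reads$strand[i] == "+") reads$start[i] + mm$offset
            else reads$end[i] - 1L - mm$offset
    ppos <- if (prow$strand == "+") gpos - prow$start
            else prow$end - 1L - gpos
    if (ppos < 0L || ppos >= prow$end - prow$start) next
    sites[[length(sites) + 1L]] <-
      data.frame(precursor = p_name, position = ppos, arm = arm_name,
                 sample = reads$sample[i], edited = reads$copies[i],
                 read = i, stringsAsFactors = FALSE)
  }
  if (length(sites) == 0L) return(empty)
  ed <- do.call(rbind, sites)
  key <- unique(ed[c("precursor", "position", "arm")])
  samples <- sort(unique(reads$sample))
  perfect <- reads[is_perfect(reads), , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(key))) {
    p_name <- key$precursor[r]; ppos <- key$position[r]
    prow <- pre[pre$name == p_name, ]
    pseq <- pre_seq(p_name)
    plen <- nchar(pseq)
    ref_base <- substring(pseq, ppos + 1L, ppos + 1L)
    if (ref_base != "A") next  # guard against inconsistent mismatch records
    tri <- paste0(
      if (ppos >= 1L) substring(pseq, ppos, ppos) else "N",
      ref_base,
      if (ppos + 2L <= plen) substring(pseq, ppos + 2L, ppos + 2L) else "N")
    gpos <- if (prow$strand == "+") prow$start + ppos else prow$end - 1L - ppos
    arm_name <- key$arm[r]
    arow <- arms[arms$name == arm_name, ]
    mat_off <- if (arow$strand == "+") gpos - arow$start + 1L
               else arow$end - 1L - gpos + 1L
    # consensus coverage: perfect, precursor-sense reads covering gpos
    cov_idx <- perfect$chrom == prow$chrom & perfect$strand == prow$strand &
      perfect$start <= gpos & perfect$end > gpos
    for (s in samples) {
      e <- sum(ed$edited[ed$precursor == p_name & ed$position == ppos &
                           ed$sample == s])
      cns <- sum(perfect$copies[cov_idx & perfect$sample == s])
      if (e + cns == 0) next
      out[[length(out) + 1L]] <-
        data.frame(precursor = p_name, position = ppos,
                   position_1based = ppos + 1L, triplet = tri,
                   arm = arm_name, mature_offset = mat_off, sample = s,
                   edited = as.numeric(e), consensus = as.numeric(cns),
                   fraction = e / (e + cns),
                   in_seed = seed_overlap_flag(mat_off),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Filter editing sites for reporting
#'
#' A site is reported when, in at least one sample, the edited fraction is
#' at least `min_fraction` *and* the site coverage (edited + consensus) is
#' at least `min_coverage`. Both thresholds are inclusive. All sample rows
#' of a passing site are kept.
#'
#' @param sites output of [scan_editing()].
#' @param min_fraction minimum edited fraction (default 0.10).
#' @param min_coverage minimum edited + consensus reads (default 20).
#' @return Subset of `sites`.
#' @export
filter_edited <- function(sites, min_fraction = 0.10, min_coverage = 20) {
  if (nrow(sites) == 0L) return(sites)
  pass <- sites$fraction >= min_fraction &
    (sites$edited + sites$consensus) >= min_coverage
  keys <- unique(sites[pass, c("precursor", "position")])
  keep <- interaction(sites$precursor, sites$position) %in%
    interaction(keys$precursor, keys$position)
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does an edited position fall in the miRNA seed?
#'
#' The seed is mature-arm nucleotides 1-7 or 2-8; positions 1 through 8
#' therefore flag as seed overlap (covering both definitions).
#'
#' @param mature_offset 1-based position of the edit on the mature arm.
#' @return Logical vector.
#' @export
seed_overlap_flag <- function(mature_offset) {
  mature_offset >= 1L & mature_offset <= 8L
}

#' Write editing sites as TSV
#' @param sites output of [scan_editing()] or [filter_edited()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_editing <- function(sites, path) {
  cols <- c("precursor", "position_1based", "triplet", "sample", "edited",
            "consensus", "fraction", "in_seed")
  utils::write.table(sites[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
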