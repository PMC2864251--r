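#' Read mapped small-RNA reads from SAM or BED
#'
#' Coordinates are normalized to 0-based half-open regardless of dialect.
#' For SAM input, per-read mismatches are recovered from the MD tag when
#' present (else assumed perfect); reads whose CIGAR contains indel or
#' clipping operations are rejected and counted in a message. Collapsed
#' read multiplicities are recovered from a `_x<N>` suffix on the read
#' name (the common collapsed-FASTA convention).
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"sam"` or `"bed"`.
#' @param sample optional sample label (`tissue.strain.replicate`) applied
#'   to every read in the file.
#' @return An [aligned_reads] object.
#' @export
read_alignments <- function(path, dialect = c("auto", "sam", "bed"),
                            sample = NA_character_) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "bed"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         sam = read_sam_alignments(path, sample),
         bed = read_bed_alignments(path, sample))
}

read_sam_alignments <- function(path, sample) {
  dest <- tempfile(fileext = "")
  bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                           indexDestination = FALSE))
  on.exit(unlink(paste0(dest, c(".bam", ".bam.bai"))), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MD", "NM"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- !bitwAnd(rec$flag, 4L)
  n_indel <- sum(mapped & grepl("[IDNSHP]", rec$cigar))
  if (n_indel > 0)
    message(n_indel, " read(s) with indel/clip CIGAR operations rejected")
  keep <- mapped & !grepl("[IDNSHP]", rec$cigar)
  if (!any(keep))
    return(aligned_reads(character(0), character(0), integer(0), integer(0),
                         character(0)))
  qname <- rec$qname[keep]
  flag <- rec$flag[keep]
  chrom <- as.character(rec$rname[keep])
  pos0 <- rec$pos[keep] - 1L
  seq_fwd <- as.character(rec$seq)[keep]
  md <- rec$tag$MD
  md <- if (is.null(md)) rep(NA_character_, length(qname)) else md[keep]
  strand <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  len <- nchar(seq_fwd)
  id_copies <- parse_copies_suffix(qname)
  mm <- mapply(decode_md, md, seq_fwd, strand, SIMPLIFY = FALSE)
  read_seq <- ifelse(strand == "-", revcomp(seq_fwd), seq_fwd)
  aligned_reads(read_id = id_copies$id, chrom = chrom, start = pos0,
                end = pos0 + len, strand = strand, sequence = read_seq,
                copies = id_copies$copies, mismatches = unname(mm),
                sample = sample)
}

# Decode a SAM MD tag into the read-orientation mismatch list.
# MD is in reference orientation; seq_fwd is the SAM SEQ (also reference
# orientation). Indels were rejected upstream, so MD holds only match
# lengths and single reference bases.
decode_md <- function(md, seq_fwd, strand) {
  if (is.na(md) || !nzchar(md)) return(empty_mismatches())
  if (grepl("\\^", md)) stop("MD tag with deletion not supported: ", md)
  toks <- regmatches(md, gregexpr("[0-9]+|[A-Z]", md))[[1]]
  ref_off <- integer(0); ref_base <- character(0)
  cur <- 0L
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      cur <- cur + as.integer(tk)
    } else {
      ref_off <- c(ref_off, cur)
      ref_base <- c(ref_base, tk)
      cur <- cur + 1L
    }
  }
  if (length(ref_off) == 0L) return(empty_mismatches())
  len <- nchar(seq_fwd)
  read_base_fwd <- substring(seq_fwd, ref_off + 1L, ref_off + 1L)
  if (strand == "+") {
    data.frame(offset = ref_off, ref = ref_base, read = read_base_fwd,
               stringsAsFactors = FALSE)
  } else {
    df <- data.frame(offset = len - 1L - ref_off,
                     ref = comp_base(ref_base),
                     read = comp_base(read_base_fwd),
                     stringsAsFactors = FALSE)
    df[order(df$offset), , drop = FALSE]
  }
}

parse_copies_suffix <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_x([0-9]+)$", ids))
  copies <- vapply(m, function(x) if (length(x) == 3) as.integer(x[3]) else 1L,
                   integer(1))
  id <- mapply(function(x, full) if (length(x) == 3) x[2] else full,
               m, ids, USE.NAMES = FALSE)
  list(id = id, copies = copies)
}

read_bed_alignments <- function(path, sample) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L)
    return(aligned_reads(character(0), character(0), integer(0), integer(0),
                         character(0)))
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else sprintf("read%06d", seq_along(gr))
  id_copies <- parse_copies_suffix(nm)
  aligned_reads(read_id = id_copies$id,
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr),
                strand = as.character(GenomicRanges::strand(gr)),
                sequence = NA_character_,
                copies = id_copies$copies,
                sample = sample)
}

#' Write aligned reads as SAM
#'
#' Sequences are emitted in reference orientation (reverse complement of
#' the stored read-orientation sequence for minus-strand reads) with MD and
#' NM tags reconstructed from the mismatch lists. Collapsed multiplicities
#' are encoded as a `_x<N>` read-name suffix (omitted when `copies == 1`).
#'
#' @param reads an [aligned_reads] object.
#' @param path output file.
#' @param chrom_lengths named integer vector of reference lengths for the
#'   `@SQ` header lines; inferred from the reads when `NULL`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(reads$end, reads$chrom, max)
    chrom_lengths <- chrom_lengths + 1000L
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  n <- nrow(reads)
  lines <- character(n)
  for (i in seq_len(n)) {
    len <- reads$end[i] - reads$start[i]
    minus <- reads$strand[i] == "-"
    seq_i <- reads$sequence[i]
    seq_fwd <- if (is.na(seq_i)) strrep("N", len)
               else if (minus) revcomp(seq_i) else seq_i
    mm <- reads$mismatches[[i]]
    md <- build_md(mm, len, minus)
    qname <- if (reads$copies[i] > 1L)
      paste0(reads$read_id[i], "_x", reads$copies[i]) else reads$read_id[i]
    lines[i] <- paste(qname, if (minus) 16L else 0L, reads$chrom[i],
                      reads$start[i] + 1L, 255L, paste0(len, "M"), "*", 0L,
                      0L, seq_fwd, "*",
                      paste0("NM:i:", nrow(mm)), paste0("MD:Z:", md),
                      sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

build_md <- function(mm, len, minus) {
  if (nrow(mm) == 0L) return(as.character(len))
  if (minus) {
    ref_off <- len - 1L - mm$offset
    ref_base <- comp_base(mm$ref)
  } else {
    ref_off <- mm$offset
    ref_base <- mm$ref
  }
  o <- order(ref_off)
  ref_off <- ref_off[o]; ref_base <- ref_base[o]
  parts <- character(0)
  prev <- -1L
  for (j in seq_along(ref_off)) {
    parts <- c(parts, as.character(ref_off[j] - prev - 1L), ref_base[j])
    prev <- ref_off[j]
  }
  paste0(paste(parts, collapse = ""), len - prev - 1L)
}

#' Write intervals as BED6
#'
#' @param df data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, and optionally `name` and `score`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  nm <- if ("name" %in% names(df)) df$name else sprintf("iv%05d", seq_len(nrow(df)))
  sc <- if ("score" %in% names(df)) df$score else 0L
  strand <- if ("strand" %in% names(df)) df$strand else "."
  lines <- paste(df$chrom, df$start, df$end, nm, sc, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

revcomp <- function(x) {
  out <- x
  ok <- !is.na(x) & nzchar(x)
  if (any(ok))
    out[ok] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(x[ok])))
  out
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}
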