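#' Construct a set of aligned small-RNA reads
#'
#' The central read container used by every stage of the pipeline: one row
#' per mapped read (or collapsed stack of identical reads), with 0-based
#' half-open genomic coordinates, the read sequence in *read* orientation
#' (5' to 3' as sequenced), and a per-read mismatch list.
#'
#' Mismatch offsets count from the read's 5' end (0-based), and `ref`/`read`
#' bases are given in read orientation, i.e. for a minus-strand read they
#' are the reverse complement of the genome-forward bases. Indels are not
#' supported: a read must satisfy `end - start == nchar(sequence)`.
#'
#' @param read_id character vector of read identifiers.
#' @param chrom character vector of reference names.
#' @param start,end integer vectors, 0-based half-open interval on the
#'   reference.
#' @param strand character vector, `"+"` or `"-"`.
#' @param sequence read bases (A/C/G/T/N) in read orientation, or `NA` when
#'   unavailable (e.g. BED input).
#' @param copies positive integer vector: number of collapsed identical
#'   reads each record represents.
#' @param mismatches a list (one element per read) of data frames with
#'   columns `offset` (0-based from the 5' end), `ref`, `read`; `NULL`
#'   means all reads are perfect matches.
#' @param sample optional character vector assigning each read to a sample
#'   label.
#'
#' @return A data frame of class `aligned_reads`.
#' @export
aligned_reads <- function(read_id, chrom, start, end, strand,
                          sequence = NA_character_, copies = 1L,
                          mismatches = NULL, sample = NA_character_) {
  n <- length(read_id)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  copies <- rep_len(as.integer(copies), n)
  sequence <- rep_len(as.character(sequence), n)
  strand <- rep_len(as.character(strand), n)
  chrom <- rep_len(as.character(chrom), n)
  sample <- rep_len(as.character(sample), n)
  if (is.null(mismatches)) mismatches <- rep(list(empty_mismatches()), n)
  stopifnot(length(start) == n, length(end) == n, length(mismatches) == n)
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(end <= start))
    stop("read intervals must satisfy start < end")
  if (any(copies < 1L))
    stop("copies must be positive")
  len <- end - start
  has_seq <- !is.na(sequence)
  if (any(has_seq & nchar(sequence) != len))
    stop("end - start must equal sequence length (indels unsupported)")
  mismatches <- lapply(mismatches, as_mismatch_df)
  for (i in seq_len(n)) {
    mm <- mismatches[[i]]
    if (nrow(mm) == 0L) next
    if (any(mm$offset < 0L) || any(mm$offset >= len[i]))
      stop("mismatch offset out of read bounds for read ", read_id[i])
    if (any(mm$ref == mm$read))
      stop("mismatch with ref == read base for read ", read_id[i])
  }
  out <- data.frame(read_id = as.character(read_id), chrom = chrom,
                    start = start, end = end, strand = strand,
                    sequence = sequence, copies = copies,
                    sample = sample, stringsAsFactors = FALSE)
  out$mismatches <- mismatches
  class(out) <- c("aligned_reads", "data.frame")
  out
}

empty_mismatches <- function() {
  data.frame(offset = integer(0), ref = character(0), read = character(0),
             stringsAsFactors = FALSE)
}

as_mismatch_df <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) return(empty_mismatches())
  stopifnot(is.data.frame(x), all(c("offset", "ref", "read") %in% names(x)))
  data.frame(offset = as.integer(x$offset), ref = toupper(as.character(x$ref)),
             read = toupper(as.character(x$read)), stringsAsFactors = FALSE)
}

#' 5' end coordinate of each read
#'
#' The 5' end is `start` for a plus-strand read and `end - 1` for a
#' minus-strand read (0-based).
#'
#' @param reads an [aligned_reads] object.
#' @return Integer vector of 5'-end positions.
#' @export
five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Number of mismatches per read
#' @param reads an [aligned_reads] object.
#' @return Integer vector.
#' @export
n_mismatches <- function(reads) {
  vapply(reads$mismatches, nrow, integer(1))
}

#' Does each read match the reference perfectly?
#' @param reads an [aligned_reads] object.
#' @return Logical vector; `TRUE` where the mismatch list is empty.
#' @export
is_perfect <- function(reads) n_mismatches(reads) == 0L

#' @export
`[.aligned_reads` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Convert reads to a GRanges (1-based, as Bioconductor expects)
#' @param reads an [aligned_reads] object.
#' @return A [GenomicRanges::GRanges] with one range per read.
#' @export
reads_granges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand)
}

#' Bind several aligned_reads objects
#' @param ... aligned_reads objects.
#' @return One combined `aligned_reads` object.
#' @export
bind_reads <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) !is.null(p) && nrow(p) > 0, logical(1))]
  if (length(parts) == 0L)
    return(aligned_reads(character(0), character(0), integer(0), integer(0),
                         character(0)))
  out <- do.call(rbind, lapply(parts, function(p) { class(p) <- "data.frame"; p }))
  class(out) <- c("aligned_reads", "data.frame")
  rownames(out) <- NULL
  out
}
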