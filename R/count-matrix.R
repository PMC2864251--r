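#' Construct a miRNA-arm count matrix
#'
#' Rows are miRNA hairpin arms (each arm, and each antisense arm, a
#' separate row); columns are samples labelled `tissue.strain.replicate`.
#'
#' @param counts non-negative numeric matrix with unique row and column
#'   names.
#' @param samples data frame with columns `label`, `tissue`, `strain`,
#'   `replicate`; derived from the column labels when `NULL`.
#' @return A matrix of class `count_matrix` carrying a `samples` attribute.
#' @export
count_matrix <- function(counts, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row and column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("row and column labels must be unique")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(samples)) samples <- parse_sample_labels(colnames(counts))
  stopifnot(identical(samples$label, colnames(counts)))
  if (anyDuplicated(samples[c("tissue", "strain", "replicate")]))
    stop("(tissue, strain, replicate) must be unique across samples")
  structure(counts, samples = samples, ocm = NULL, removed_rows = NULL,
            class = c("count_matrix", "matrix", "array"))
}

#' Parse `tissue.strain.replicate` sample labels
#' @param labels character vector.
#' @return Data frame with columns `label`, `tissue`, `strain`, `replicate`.
#' @export
parse_sample_labels <- function(labels) {
  parts <- strsplit(labels, ".", fixed = TRUE)
  if (any(lengths(parts) != 3))
    stop("sample labels must have the form tissue.strain.replicate")
  data.frame(label = labels,
             tissue = vapply(parts, `[`, "", 1),
             strain = vapply(parts, `[`, "", 2),
             replicate = as.integer(vapply(parts, `[`, "", 3)),
             stringsAsFactors = FALSE)
}

#' Sample metadata of a count matrix
#' @param m a [count_matrix].
#' @return The `samples` data frame.
#' @export
sample_info <- function(m) attr(m, "samples")

#' Per-sample outlier-corrected means of a normalized matrix
#' @param m a [count_matrix] returned by [ocm_normalize()].
#' @return Named numeric vector, or `NULL` if not normalized.
#' @export
ocm_values <- function(m) attr(m, "ocm")

#' Has the matrix been ocm-normalized?
#' @param m a [count_matrix].
#' @return Logical.
#' @export
is_normalized <- function(m) !is.null(attr(m, "ocm"))

#' Quantify miRNA arm expression from mapped reads
#'
#' Only perfectly matching reads are counted. A read counts toward an arm
#' when its interval overlaps the arm by at least `min_overlap` of the read
#' length; same-strand overlap counts toward the arm itself, opposite-strand
#' overlap toward a separate antisense row named `<arm>(as)`. When a read
#' overlaps two arms equally the tie goes to the 5' arm of the precursor
#' (reported in a message). Collapsed-read `copies` are honored.
#'
#' @param reads an [aligned_reads] object with a `sample` label per read.
#' @param ann an [annotation_set] containing `mirna_arm` features.
#' @param min_overlap minimum overlap as a fraction of read length
#'   (default 0.5).
#' @return A [count_matrix] with one row per sense arm (plus antisense rows
#'   that received reads) and one column per sample.
#' @export
quantify <- function(reads, ann, min_overlap = 0.5) {
  if (any(is.na(reads$sample)))
    stop("every read must carry a sample assignment")
  arms <- ann[ann$class == "mirna_arm", , drop = FALSE]
  if (nrow(arms) == 0L) stop("annotation contains no mirna_arm features")
  perfect <- reads[is_perfect(reads), , drop = FALSE]
  asg <- assign_arms(perfect, arms, min_overlap)
  sample_labels <- sort(unique(reads$sample))
  sense_rows <- arms$name
  as_rows <- sort(unique(asg$row[asg$antisense]))
  all_rows <- c(sense_rows, as_rows)
  counts <- matrix(0, nrow = length(all_rows), ncol = length(sample_labels),
                   dimnames = list(all_rows, sample_labels))
  if (nrow(asg) > 0) {
    agg <- stats::aggregate(copies ~ row + sample, data = asg, FUN = sum)
    counts[cbind(agg$row, agg$sample)] <- agg$copies
  }
  count_matrix(counts)
}

# Assign each read to its best-overlapping arm. Returns a data frame with
# one row per assigned read: row (arm row label), sample, copies, read index.
assign_arms <- function(reads, arms, min_overlap) {
  empty <- data.frame(read = integer(0), row = character(0),
                      sample = character(0), copies = integer(0),
                      antisense = logical(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  rgr <- reads_granges(reads)
  agr <- annotation_granges(arms)
  hits <- GenomicRanges::findOverlaps(rgr, agr, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(rgr)[qh], IRanges::ranges(agr)[sh]))
  len <- reads$end[qh] - reads$start[qh]
  keep <- ov >= min_overlap * len
  qh <- qh[keep]; sh <- sh[keep]; ov <- ov[keep]
  if (length(qh) == 0L) return(empty)
  # per read pick the arm with the largest overlap; ties -> 5' arm
  pick <- integer(0)
  n_ties <- 0L
  for (r in unique(qh)) {
    idx <- which(qh == r)
    best <- idx[ov[idx] == max(ov[idx])]
    if (length(best) > 1L) {
      n_ties <- n_ties + 1L
      cand <- sh[best]
      # 5' arm: smaller start on a + precursor, larger end on a - precursor
      if (arms$strand[cand[1]] == "+") {
        best <- best[order(arms$start[cand], arms$name[cand])][1]
      } else {
        best <- best[order(-arms$end[cand], arms$name[cand])][1]
      }
    }
    pick <- c(pick, best)
  }
  if (n_ties > 0L)
    message(n_ties, " read(s) overlapped two arms equally; assigned to the 5' arm")
  ridx <- qh[pick]
  aidx <- sh[pick]
  antisense <- reads$strand[ridx] != arms$strand[aidx]
  row <- ifelse(antisense, paste0(arms$name[aidx], "(as)"), arms$name[aidx])
  data.frame(read = ridx, row = row, sample = reads$sample[ridx],
             copies = reads$copies[ridx], antisense = antisense,
             stringsAsFactors = FALSE)
}

#' Write a count matrix as TSV
#'
#' `#`-prefixed header lines carry the sample table and, for normalized
#' matrices, the per-sample ocm and removed rows, so that
#' [read_count_matrix()] round-trips the object exactly.
#'
#' @param m a [count_matrix].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  smp <- sample_info(m)
  hdr <- sprintf("#sample\t%s\t%s\t%s\t%d", smp$label, smp$tissue,
                 smp$strain, smp$replicate)
  ocm <- ocm_values(m)
  if (!is.null(ocm)) {
    rem <- attr(m, "removed_rows")
    hdr <- c(hdr,
             sprintf("#ocm\t%s\t%s", names(ocm), format(ocm, digits = 17)),
             sprintf("#removed\t%s\t%s", names(rem),
                     vapply(rem, paste, "", collapse = ",")))
  }
  body <- c(paste(c("#id", colnames(m)), collapse = "\t"),
            paste(rownames(m),
                  apply(m, 1, function(r) paste(format(r, digits = 17,
                                                       trim = TRUE,
                                                       scientific = FALSE),
                                                collapse = "\t")),
                  sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param path TSV file.
#' @return A [count_matrix].
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#(sample|ocm|removed)\t", lines)
  meta <- strsplit(lines[is_meta], "\t", fixed = TRUE)
  body <- lines[!is_meta]
  header <- strsplit(sub("^#", "", body[1]), "\t", fixed = TRUE)[[1]]
  labels <- header[-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, "", 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(labels))))
  if (length(labels) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(ids, labels)
  smp_meta <- meta[vapply(meta, `[`, "", 1) == "#sample"]
  samples <- data.frame(label = vapply(smp_meta, `[`, "", 2),
                        tissue = vapply(smp_meta, `[`, "", 3),
                        strain = vapply(smp_meta, `[`, "", 4),
                        replicate = as.integer(vapply(smp_meta, `[`, "", 5)),
                        stringsAsFactors = FALSE)
  samples <- samples[match(labels, samples$label), ]
  rownames(samples) <- NULL
  m <- count_matrix(vals, samples)
  ocm_meta <- meta[vapply(meta, `[`, "", 1) == "#ocm"]
  if (length(ocm_meta) > 0) {
    ocm <- as.numeric(vapply(ocm_meta, `[`, "", 3))
    names(ocm) <- vapply(ocm_meta, `[`, "", 2)
    attr(m, "ocm") <- ocm[labels]
    rem_meta <- meta[vapply(meta, `[`, "", 1) == "#removed"]
    rem <- lapply(rem_meta, function(x) strsplit(x[3], ",", fixed = TRUE)[[1]])
    names(rem) <- vapply(rem_meta, `[`, "", 2)
    attr(m, "removed_rows") <- rem[labels]
  }
  m
}
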