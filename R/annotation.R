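#' Construct an annotation set
#'
#' Genomic features used by the pipeline: miRNA hairpin arms and their
#' precursors, structural RNA genes to filter out before piRNA cluster
#' calling, coding genes and repeats. Coordinates are 0-based half-open
#' internally (converted at the GFF/BED boundary).
#'
#' @param chrom,start,end,strand feature coordinates (0-based half-open).
#' @param class feature class, one of `mirna_arm`, `pre_mirna`, `repeat`,
#'   `gene`, `snoRNA`, `scRNA`, `rRNA`.
#' @param name unique feature name (within its class).
#' @param parent for `mirna_arm` features, the name of the parent
#'   `pre_mirna`; `NA` otherwise.
#' @return A data frame of class `annotation_set`.
#' @export
annotation_set <- function(chrom, start, end, strand, class, name,
                           parent = NA_character_) {
  n <- length(name)
  out <- data.frame(chrom = as.character(chrom),
                    start = as.integer(start), end = as.integer(end),
                    strand = rep_len(as.character(strand), n),
                    class = rep_len(as.character(class), n),
                    name = as.character(name),
                    parent = rep_len(as.character(parent), n),
                    stringsAsFactors = FALSE)
  validate_annotation_set(out)
  class(out) <- c("annotation_set", "data.frame")
  out
}

ANNOTATION_CLASSES <- c("mirna_arm", "pre_mirna", "repeat", "gene",
                        "snoRNA", "scRNA", "rRNA")

validate_annotation_set <- function(ann) {
  if (any(ann$end <= ann$start))
    stop("annotation intervals must satisfy start < end")
  if (any(!ann$class %in% ANNOTATION_CLASSES))
    stop("unknown feature class: ",
         paste(setdiff(unique(ann$class), ANNOTATION_CLASSES), collapse = ", "))
  for (cl in unique(ann$class)) {
    nm <- ann$name[ann$class == cl]
    if (anyDuplicated(nm))
      stop("duplicate feature names within class '", cl, "': ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  arms <- ann[ann$class == "mirna_arm", , drop = FALSE]
  if (nrow(arms) > 0) {
    if (any(is.na(arms$parent)))
      stop("mirna_arm features must carry a parent pre_mirna name")
    pre <- ann$name[ann$class == "pre_mirna"]
    orphan <- setdiff(arms$parent, pre)
    if (length(orphan) > 0)
      stop("mirna_arm features with unresolvable parent: ",
           paste(orphan, collapse = ", "))
  }
  invisible(ann)
}

#' @export
`[.annotation_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- c("annotation_set", "data.frame")
  out
}

#' Convert an annotation set (or a class subset) to GRanges
#' @param ann an [annotation_set].
#' @param classes optional character vector restricting feature classes.
#' @return A [GenomicRanges::GRanges] with `name`, `class`, `parent` columns.
#' @export
annotation_granges <- function(ann, classes = NULL) {
  if (!is.null(classes)) ann <- ann[ann$class %in% classes, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$name <- ann$name
  S4Vectors::mcols(gr)$class <- ann$class
  S4Vectors::mcols(gr)$parent <- ann$parent
  gr
}

#' Read genomic annotation from a GFF3 file
#'
#' GFF3 `type` values are mapped onto the pipeline's feature classes via a
#' configurable table; 1-based GFF coordinates become 0-based half-open.
#' `Parent` attributes resolve arm-to-precursor links.
#'
#' @param path a GFF3 file.
#' @param type_map named character vector mapping GFF3 `type` to annotation
#'   class. Types absent from the map are dropped.
#' @return An [annotation_set].
#' @export
read_annotation <- function(path, type_map = default_type_map()) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type %in% names(type_map)
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0L) stop("no mappable features in ", path)
  name <- as.character(gr$ID)
  if (all(is.na(name)) && !is.null(gr$Name)) name <- as.character(gr$Name)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p) == 0) NA_character_ else as.character(p[1]), character(1))
  annotation_set(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr) - 1L,
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)),
                 class = unname(type_map[type]),
                 name = name, parent = parent)
}

#' Default GFF3 type-to-class map
#' @return Named character vector.
#' @export
default_type_map <- function() {
  c(miRNA = "mirna_arm", mirna_arm = "mirna_arm",
    miRNA_primary_transcript = "pre_mirna", pre_mirna = "pre_mirna",
    repeat_region = "repeat", dispersed_repeat = "repeat",
    gene = "gene", snoRNA = "snoRNA", scRNA = "scRNA", rRNA = "rRNA")
}

#' Write an annotation set as GFF3
#' @param ann an [annotation_set].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  inv_map <- c(mirna_arm = "miRNA", pre_mirna = "miRNA_primary_transcript",
               "repeat" = "repeat_region", gene = "gene", snoRNA = "snoRNA",
               scRNA = "scRNA", rRNA = "rRNA")
  attrs <- paste0("ID=", ann$name,
                  ifelse(is.na(ann$parent), "", paste0(";Parent=", ann$parent)))
  lines <- paste(ann$chrom, "srnatlas", inv_map[ann$class],
                 ann$start + 1L, ann$end, ".", ann$strand, ".", attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
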