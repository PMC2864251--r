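#' piRNA cluster detection parameters
#'
#' @param core_window window length in bp within which unique start
#'   positions are counted (default 2000).
#' @param core_min_starts a core requires strictly more than this many
#'   unique same-strand start positions within `core_window` (default 20,
#'   i.e. 21 qualify).
#' @param extension_gap a cluster boundary keeps extending while the next
#'   same-strand start lies within this many bp (default 1000).
#' @param merge_gap adjacent clusters (any strand) closer than this are
#'   merged into one location (default 1000).
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(core_window = 2000, core_min_starts = 20,
                           extension_gap = 1000, merge_gap = 1000) {
  stopifnot(core_window > 0, core_min_starts >= 1, extension_gap > 0,
            merge_gap > 0)
  structure(list(core_window = as.integer(core_window),
                 core_min_starts = as.integer(core_min_starts),
                 extension_gap = as.integer(extension_gap),
                 merge_gap = as.integer(merge_gap)),
            class = "cluster_params")
}

#' Remove reads overlapping structural annotation
#'
#' Drops reads overlapping (any overlap, strand-agnostic) features of
#' classes `mirna_arm`, `pre_mirna`, `snoRNA`, `scRNA`, `rRNA` or `gene`,
#' so that piRNA cluster calling sees only unannotated small RNAs.
#'
#' @param reads an [aligned_reads] object.
#' @param ann an [annotation_set].
#' @return The retained reads.
#' @export
filter_structural <- function(reads, ann) {
  classes <- c("mirna_arm", "pre_mirna", "snoRNA", "scRNA", "rRNA", "gene")
  feats <- ann[ann$class %in% classes, , drop = FALSE]
  if (nrow(feats) == 0L || nrow(reads) == 0L) return(reads)
  hits <- GenomicRanges::findOverlaps(reads_granges(reads),
                                      annotation_granges(feats),
                                      ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0L) return(reads)
  reads[-drop, , drop = FALSE]
}

#' Unique 5' start positions per chromosome and strand
#'
#' Clonal amplification and cloning bias inflate read counts at single
#' positions, so cluster detection considers each distinct 5' start
#' position once. The 5' position is `start` for plus reads and `end - 1`
#' for minus reads.
#'
#' @param reads an [aligned_reads] object.
#' @return Data frame with columns `chrom`, `strand`, `pos`, sorted by
#'   chrom, strand, position.
#' @export
unique_starts <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.frame(chrom = character(0), strand = character(0),
                      pos = integer(0), stringsAsFactors = FALSE))
  df <- data.frame(chrom = reads$chrom, strand = reads$strand,
                   pos = five_prime(reads), stringsAsFactors = FALSE)
  df <- unique(df)
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Detect piRNA cluster cores
#'
#' A core exists wherever more than `core_min_starts` unique same-strand
#' start positions fall within a `core_window`-bp window: scanning windows
#' anchored on the starts themselves, positions i..i+core_min_starts
#' qualify when `starts[i + core_min_starts] - starts[i] < core_window`.
#' Overlapping qualifying windows coalesce into one core spanning their
#' union.
#'
#' @param starts sorted integer vector of unique start positions (one
#'   chromosome, one strand).
#' @param params a [cluster_params] list.
#' @return Data frame of core intervals (`start`, `end`, 0-based half-open
#'   over start positions; `end` is the last qualifying start + 1).
#' @export
detect_cores <- function(starts, params = cluster_params()) {
  starts <- as.integer(starts)
  if (is.unsorted(starts, strictly = TRUE)) starts <- sort(unique(starts))
  K <- params$core_min_starts
  n <- length(starts)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < K + 1L) return(empty)
  i <- seq_len(n - K)
  qual <- i[starts[i + K] - starts[i] < params$core_window]
  if (length(qual) == 0L) return(empty)
  # coalesce overlapping qualifying windows [starts[i], starts[i+K]]
  win_start <- starts[qual]
  win_end <- starts[qual + K]
  out_s <- integer(0); out_e <- integer(0)
  cs <- win_start[1]; ce <- win_end[1]
  for (j in seq_along(qual)[-1]) {
    if (win_start[j] <= ce) {
      ce <- max(ce, win_end[j])
    } else {
      out_s <- c(out_s, cs); out_e <- c(out_e, ce)
      cs <- win_start[j]; ce <- win_end[j]
    }
  }
  out_s <- c(out_s, cs); out_e <- c(out_e, ce)
  data.frame(start = out_s, end = out_e + 1L)
}

#' Extend a cluster core along nearby same-strand starts
#'
#' From the core, the boundary keeps absorbing the nearest same-strand
#' unique start while it lies within `extension_gap` bp of the current
#' boundary, on each side independently; extension stops on a side when the
#' next start is farther away. The final interval spans the first to the
#' last absorbed start (+1 for the half-open end), and `n_unique_starts`
#' counts all absorbed starts.
#'
#' @param core one row of [detect_cores()] output (list or data frame row
#'   with `start`, `end`).
#' @param starts the full sorted vector of unique starts for the same
#'   chromosome/strand.
#' @param params a [cluster_params] list.
#' @return List with `start`, `end`, `n_unique_starts`.
#' @export
extend_cluster <- function(core, starts, params = cluster_params()) {
  starts <- sort(unique(as.integer(starts)))
  gap <- params$extension_gap
  j <- min(which(starts >= core$start))
  k <- max(which(starts <= core$end - 1L))
  while (j > 1L && starts[j] - starts[j - 1L] <= gap) j <- j - 1L
  while (k < length(starts) && starts[k + 1L] - starts[k] <= gap) k <- k + 1L
  list(start = starts[j], end = starts[k] + 1L, n_unique_starts = k - j + 1L)
}

#' Call strand-specific piRNA clusters
#'
#' Full pipeline for one read set: structural-annotation filtering (when
#' `ann` is given), unique-start reduction, per-(chromosome, strand) core
#' detection and extension.
#'
#' @param reads an [aligned_reads] object.
#' @param ann optional [annotation_set] for [filter_structural()].
#' @param params a [cluster_params] list.
#' @return Data frame of clusters: `chrom`, `start`, `end`, `strand`,
#'   `n_unique_starts`.
#' @export
call_pirna_clusters <- function(reads, ann = NULL, params = cluster_params()) {
  if (!is.null(ann)) reads <- filter_structural(reads, ann)
  us <- unique_starts(reads)
  out <- list()
  for (ch in unique(us$chrom)) for (st in c("+", "-")) {
    pos <- us$pos[us$chrom == ch & us$strand == st]
    if (length(pos) == 0L) next
    cores <- detect_cores(pos, params)
    for (r in seq_len(nrow(cores))) {
      cl <- extend_cluster(cores[r, ], pos, params)
      out[[length(out) + 1L]] <-
        data.frame(chrom = ch, start = cl$start, end = cl$end, strand = st,
                   n_unique_starts = cl$n_unique_starts,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_unique_starts = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  # extension can make same-strand clusters coincide; deduplicate
  res <- unique(res)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge adjacent clusters into locations
#'
#' Clusters on either strand whose intervals overlap or lie within
#' `merge_gap` bp are united into one location. Two-strand locations are
#' classified by geometry: `divergent` when the minus-strand member lies
#' upstream (left) of the plus-strand member so transcription points
#' outwards from a central origin, `convergent` when transcription points
#' inwards, `tandem` otherwise; single-member locations are `single`.
#'
#' @param clusters data frame from [call_pirna_clusters()].
#' @param params a [cluster_params] list.
#' @return Data frame of merged locations: `chrom`, `start`, `end`,
#'   `n_members`, `strands`, `orientation_class`, `n_unique_starts`,
#'   `members` (comma-separated member lineage).
#' @export
merge_adjacent <- function(clusters, params = cluster_params()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      strands = character(0), orientation_class = character(0),
                      n_unique_starts = integer(0), members = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L) return(empty)
  cl <- clusters[order(clusters$chrom, clusters$start, clusters$end), ,
                 drop = FALSE]
  cl$member_id <- sprintf("%s:%d-%d(%s)", cl$chrom, cl$start, cl$end,
                          cl$strand)
  out <- list()
  grp_rows <- list()
  cur <- cl[1, , drop = FALSE]
  cur_end <- cl$end[1]
  flush <- function(rows) {
    strands <- unique(rows$strand)
    n <- nrow(rows)
    oc <- if (n == 1L) "single"
    else if (length(strands) == 2L && sum(rows$strand == "-") == 1L &&
             sum(rows$strand == "+") == 1L) {
      minus <- rows[rows$strand == "-", ]
      plus <- rows[rows$strand == "+", ]
      if (minus$start + minus$end <= plus$start + plus$end) "divergent"
      else "convergent"
    } else "tandem"
    data.frame(chrom = rows$chrom[1], start = min(rows$start),
               end = max(rows$end), n_members = n,
               strands = paste(sort(strands), collapse = ""),
               orientation_class = oc,
               n_unique_starts = sum(rows$n_unique_starts),
               members = paste(rows$member_id, collapse = ","),
               stringsAsFactors = FALSE)
  }
  rows <- cl[1, , drop = FALSE]
  for (i in seq_len(nrow(cl))[-1]) {
    same <- cl$chrom[i] == rows$chrom[1] &&
      cl$start[i] - max(rows$end) <= params$merge_gap
    if (same) {
      rows <- rbind(rows, cl[i, , drop = FALSE])
    } else {
      out[[length(out) + 1L]] <- flush(rows)
      rows <- cl[i, , drop = FALSE]
    }
  }
  out[[length(out) + 1L]] <- flush(rows)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genomic characteristics of piRNA cluster locations
#'
#' Summarizes (a) gene density inside vs outside clusters (genes counted by
#' any overlap, plus those completely within a cluster), (b) repeat-covered
#' base fraction inside vs outside, and (c) the fraction of cluster bases
#' with conservation score > `cons_threshold` vs the genome background.
#'
#' @param locations data frame of cluster locations (`chrom`, `start`,
#'   `end`).
#' @param genes an [annotation_set] of class-`gene` features, or `NULL`.
#' @param repeats an [annotation_set] of class-`repeat` features, or `NULL`.
#' @param conservation bedGraph-style data frame (`chrom`, `start`, `end`,
#'   `score`), or `NULL`.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param cons_threshold conservation score cutoff (default 0.5).
#' @return One-row data frame of summary statistics (all `NA` when there
#'   are no clusters).
#' @export
cluster_characteristics <- function(locations, genes = NULL, repeats = NULL,
                                    conservation = NULL, chrom_lengths,
                                    cons_threshold = 0.5) {
  na_row <- data.frame(cluster_bp = NA_real_, genes_inside = NA_real_,
                       genes_fully_inside = NA_real_,
                       gene_density_inside = NA_real_,
                       gene_density_outside = NA_real_,
                       gene_density_ratio = NA_real_,
                       repeat_frac_inside = NA_real_,
                       repeat_frac_outside = NA_real_,
                       conserved_frac_inside = NA_real_,
                       conserved_frac_genome = NA_real_)
  if (is.null(locations) || nrow(locations) == 0L) return(na_row)
  loc_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    locations$chrom,
    IRanges::IRanges(locations$start + 1L, locations$end)))
  genome_bp <- sum(as.numeric(chrom_lengths))
  cluster_bp <- sum(as.numeric(GenomicRanges::width(loc_gr)))
  outside_bp <- genome_bp - cluster_bp
  out <- na_row
  out$cluster_bp <- cluster_bp
  if (!is.null(genes) && nrow(genes) > 0L) {
    ggr <- annotation_granges(genes, "gene")
    ov <- GenomicRanges::countOverlaps(ggr, loc_gr, ignore.strand = TRUE) > 0
    within <- GenomicRanges::countOverlaps(ggr, loc_gr, type = "within",
                                           ignore.strand = TRUE) > 0
    out$genes_inside <- as.numeric(sum(ov))
    out$genes_fully_inside <- as.numeric(sum(within))
    out$gene_density_inside <- sum(ov) / (cluster_bp / 1e6)
    out$gene_density_outside <- sum(!ov) / (outside_bp / 1e6)
    out$gene_density_ratio <- out$gene_density_inside / out$gene_density_outside
  }
  if (!is.null(repeats) && nrow(repeats) > 0L) {
    rgr <- GenomicRanges::reduce(annotation_granges(repeats, "repeat"),
                                 ignore.strand = TRUE)
    inside <- sum(as.numeric(GenomicRanges::width(
      GenomicRanges::intersect(rgr, loc_gr, ignore.strand = TRUE))))
    total <- sum(as.numeric(GenomicRanges::width(rgr)))
    out$repeat_frac_inside <- inside / cluster_bp
    out$repeat_frac_outside <- (total - inside) / outside_bp
  }
  if (!is.null(conservation) && nrow(conservation) > 0L) {
    cons <- conservation[conservation$score > cons_threshold, , drop = FALSE]
    if (nrow(cons) > 0L) {
      cgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        cons$chrom, IRanges::IRanges(cons$start + 1L, cons$end)))
      inside <- sum(as.numeric(GenomicRanges::width(
        GenomicRanges::intersect(cgr, loc_gr, ignore.strand = TRUE))))
      total <- sum(as.numeric(GenomicRanges::width(cgr)))
      out$conserved_frac_inside <- inside / cluster_bp
      out$conserved_frac_genome <- total / genome_bp
    } else {
      out$conserved_frac_inside <- 0
      out$conserved_frac_genome <- 0
    }
  }
  out
}
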