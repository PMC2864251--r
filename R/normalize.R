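#' Outlier-corrected-mean (ocm) normalization
#'
#' A handful of extremely abundant miRNAs (e.g. the liver-dominant
#' mir-122-5p, which alone can hold over 20% of a liver library) would
#' dominate a plain mean. Per sample, the three highest-covered rows are
#' therefore removed before taking the arithmetic mean of the remaining
#' counts (zeros included); every count in the column is then divided by
#' this outlier-corrected mean. The median is deliberately not used as the
#' normalizer because small RNA libraries contain many lowly covered rows.
#'
#' Ties at the third-highest count are broken lexicographically by row
#' label so that exactly three rows are removed, deterministically.
#'
#' @param m a raw [count_matrix]; every column must have at least four rows
#'   with nonzero counts.
#' @return A normalized [count_matrix] with attributes `ocm` (named
#'   per-sample divisor) and `removed_rows` (per-sample excluded row ids).
#' @export
ocm_normalize <- function(m) {
  if (is_normalized(m)) stop("matrix is already normalized")
  nonzero <- colSums(m > 0)
  if (any(nonzero <= 3))
    stop("normalization undefined: column(s) with <= 3 nonzero rows: ",
         paste(colnames(m)[nonzero <= 3], collapse = ", "))
  ocm <- numeric(ncol(m)); names(ocm) <- colnames(m)
  removed <- vector("list", ncol(m)); names(removed) <- colnames(m)
  norm <- m
  for (j in seq_len(ncol(m))) {
    ord <- order(-m[, j], rownames(m))
    drop3 <- ord[1:3]
    removed[[j]] <- rownames(m)[drop3]
    ocm[j] <- mean(m[-drop3, j])
    norm[, j] <- m[, j] / ocm[j]
  }
  attr(norm, "ocm") <- ocm
  attr(norm, "removed_rows") <- removed
  norm
}

# Half-read pseudocount floor on the normalized scale: 0.5 / ocm per sample.
epsilon_floor <- function(m) {
  ocm <- ocm_values(m)
  if (is.null(ocm)) stop("matrix must be ocm-normalized")
  0.5 / ocm
}

# Average replicates: returns list(values = 3d array row x tissue x strain,
# eps = matrix tissue x strain of averaged pseudocount floors).
average_replicates <- function(m) {
  smp <- sample_info(m)
  tissues <- unique(smp$tissue); strains <- unique(smp$strain)
  eps_col <- epsilon_floor(m)
  v <- array(NA_real_, dim = c(nrow(m), length(tissues), length(strains)),
             dimnames = list(rownames(m), tissues, strains))
  eps <- matrix(NA_real_, length(tissues), length(strains),
                dimnames = list(tissues, strains))
  for (t in tissues) for (s in strains) {
    cols <- smp$label[smp$tissue == t & smp$strain == s]
    if (length(cols) == 0)
      stop("no sample for tissue '", t, "', strain '", s, "'")
    v[, t, s] <- rowMeans(m[, cols, drop = FALSE])
    eps[t, s] <- mean(eps_col[cols])
  }
  list(values = v, eps = eps, tissues = tissues, strains = strains)
}

#' Call tissue-specific miRNAs
#'
#' A row is specific for a tissue when its normalized value there is at
#' least `fold` times the maximum over all other tissues, in every strain
#' individually (replicates averaged first). Values are floored at the
#' half-read pseudocount (0.5/ocm) before forming ratios so that zero
#' denominators are defined; the threshold is inclusive ("at least").
#'
#' @param m an ocm-normalized [count_matrix] covering at least two tissues.
#' @param fold fold-change threshold (default 5).
#' @return Data frame with columns `row`, `tissue`, `direction`
#'   (`"specific"`), `fold_threshold`.
#' @export
call_specific <- function(m, fold = 5) {
  specificity_calls(m, fold, "specific")
}

#' Call tissue-avoidant miRNAs
#'
#' Mirror of [call_specific()]: a row is avoidant in a tissue when its
#' (pseudocount-floored) normalized value there is at most `1/fold` of the
#' minimum over all other tissues, in every strain individually.
#'
#' @inheritParams call_specific
#' @return Data frame with `direction == "avoidant"`.
#' @export
call_avoidant <- function(m, fold = 5) {
  specificity_calls(m, fold, "avoidant")
}

specificity_calls <- function(m, fold, direction) {
  if (!is_normalized(m)) stop("matrix must be ocm-normalized")
  avg <- average_replicates(m)
  if (length(avg$tissues) < 2) stop("at least two tissues required")
  v <- avg$values
  # pseudocount floor, per (tissue, strain)
  for (t in avg$tissues) for (s in avg$strains)
    v[, t, s] <- pmax(v[, t, s], avg$eps[t, s])
  out <- list()
  for (t in avg$tissues) {
    others <- setdiff(avg$tissues, t)
    hit <- rep(TRUE, nrow(m))
    for (s in avg$strains) {
      if (direction == "specific") {
        ref <- apply(v[, others, s, drop = FALSE], 1, max)
        hit <- hit & (v[, t, s] >= fold * ref)
      } else {
        ref <- apply(v[, others, s, drop = FALSE], 1, min)
        hit <- hit & (v[, t, s] <= ref / fold)
      }
    }
    if (any(hit))
      out[[t]] <- data.frame(row = rownames(m)[hit], tissue = t,
                             direction = direction, fold_threshold = fold,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(row = character(0), tissue = character(0),
                      direction = character(0), fold_threshold = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Between-sample rank correlations
#'
#' Spearman's rho between normalized expression profiles, computed per pair
#' over the rows expressed (nonzero) in at least one of the two samples.
#'
#' @param m an ocm-normalized [count_matrix] with at least two columns.
#' @param method correlation method passed to [stats::cor()]
#'   (default `"spearman"`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(m, method = "spearman") {
  if (ncol(m) < 2) stop("at least two samples required")
  k <- ncol(m)
  rho <- diag(1, k)
  dimnames(rho) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    keep <- m[, i] > 0 | m[, j] > 0
    rho[i, j] <- rho[j, i] <- stats::cor(m[keep, i], m[keep, j],
                                         method = method)
  }
  rho
}

#' Hierarchical clustering of miRNA expression profiles
#'
#' Euclidean distances between rows of `log10(normalized value + eps)`
#' (eps = half-read pseudocount per sample), clustered agglomeratively.
#' The log10 matrix is what heatmap exports should show.
#'
#' @param m an ocm-normalized [count_matrix].
#' @param linkage agglomeration method for [stats::hclust()]
#'   (default `"complete"`).
#' @return List with `order` (row labels in leaf order), `hclust` (the
#'   merge tree), and `log_values` (the log10 matrix).
#' @export
mirna_tree <- function(m, linkage = "complete") {
  if (!is_normalized(m)) stop("matrix must be ocm-normalized")
  if (nrow(m) < 2) stop("at least two rows required")
  eps <- epsilon_floor(m)
  lv <- log10(sweep(unclass(m), 2, eps, `+`))
  h <- stats::hclust(stats::dist(lv), method = linkage)
  list(order = rownames(m)[h$order], hclust = h, log_values = lv)
}

#' Write a heatmap matrix (log10 normalized values, tree-ordered rows)
#' @param tree result of [mirna_tree()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(tree, path) {
  lv <- tree$log_values[tree$order, , drop = FALSE]
  lines <- c(paste(c("#id", colnames(lv)), collapse = "\t"),
             paste(rownames(lv),
                   apply(lv, 1, function(r) paste(format(r, digits = 6),
                                                  collapse = "\t")),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
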