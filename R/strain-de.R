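#' Sliding-window strain-differential expression test
#'
#' For each miRNA, the strain means of ocm-normalized expression are
#' summarized as an abundance A = (mB + mS)/2 and a log-ratio
#' D = log2(mB/mS). Because count noise shrinks with abundance, D's null
#' mean and standard deviation are estimated locally: rows are ordered by A
#' and, for every row, the mean and SD of D are taken over a window of
#' `window` rows centered on it. The (window-1)/2 rows at each extreme
#' reuse the window statistics of the first fully interior row ("identical
#' values at both extremes"). Each row's Z = (D - win_mean)/win_sd is
#' converted to a one-sided normal tail probability in the direction of its
#' own deviation, and Benjamini-Hochberg adjusted.
#'
#' @param m an ocm-normalized [count_matrix].
#' @param group_a,group_b strain labels; D = log2(mean_a / mean_b).
#' @param tissue optional tissue restriction (e.g. `"liver"`); `NULL` uses
#'   all columns.
#' @param window odd window size (default 41).
#' @param alpha FDR significance level (default 0.05).
#' @param extreme_mode how the window behaves at the extremes:
#'   `"reuse"` (rows within half a window of an end reuse the first/last
#'   interior row's statistics, the default) or `"pad"` (the D vector is
#'   padded with replicated extreme values and the window slides normally).
#' @param direction `"observed"` (default) tests each row in the direction
#'   of its own deviation, p = P(X > |Z|); `"literal"` applies p = P(X > Z)
#'   so only group_a-up rows are discoverable.
#' @return Data frame (rows in ascending-A order) with columns `id`, `mB`,
#'   `mS`, `A`, `D`, `win_mean`, `win_sd`, `Z`, `p`, `q`, `significant`.
#' @export
sliding_window_de <- function(m, group_a = "BN-Lx", group_b = "SHR",
                              tissue = NULL, window = 41, alpha = 0.05,
                              extreme_mode = c("reuse", "pad"),
                              direction = c("observed", "literal")) {
  extreme_mode <- match.arg(extreme_mode)
  direction <- match.arg(direction)
  if (!is_normalized(m)) stop("matrix must be ocm-normalized")
  if (window %% 2 != 1 || window < 3) stop("window must be an odd integer >= 3")
  smp <- sample_info(m)
  ocm <- ocm_values(m)
  m <- unclass(m)
  if (!is.null(tissue)) {
    keep <- smp$tissue == tissue
    m <- m[, smp$label[keep], drop = FALSE]
    smp <- smp[keep, , drop = FALSE]
  }
  cols_a <- smp$label[smp$strain == group_a]
  cols_b <- smp$label[smp$strain == group_b]
  if (length(cols_a) < 1 || length(cols_b) < 1)
    stop("both strains need at least one replicate")
  mB <- rowMeans(m[, cols_a, drop = FALSE])
  mS <- rowMeans(m[, cols_b, drop = FALSE])
  keep <- !(mB == 0 & mS == 0)
  mB <- mB[keep]; mS <- mS[keep]
  n <- length(mB)
  if (n < window)
    stop("need at least ", window, " rows after filtering, got ", n)
  eps <- 0.5 / mean(ocm[c(cols_a, cols_b)])
  A <- (mB + mS) / 2
  D <- log2(pmax(mB, eps) / pmax(mS, eps))
  ord <- order(A, names(mB))
  id <- names(mB)[ord]
  A <- A[ord]; D <- D[ord]; mB <- mB[ord]; mS <- mS[ord]
  half <- (window - 1L) / 2L
  stats <- window_stats(D, window, extreme_mode)
  if (any(stats$sd == 0))
    stop("window with zero SD of D (all values identical); ",
         "review pseudocount/jitter settings")
  Z <- (D - stats$mean) / stats$sd
  p <- if (direction == "observed") stats::pnorm(abs(Z), lower.tail = FALSE)
       else stats::pnorm(Z, lower.tail = FALSE)
  q <- bh_fdr(p)
  data.frame(id = id, mB = mB, mS = mS, A = A, D = D,
             win_mean = stats$mean, win_sd = stats$sd, Z = Z, p = p, q = q,
             significant = q < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

window_stats <- function(D, window, extreme_mode) {
  n <- length(D)
  half <- (window - 1L) / 2L
  wm <- numeric(n); ws <- numeric(n)
  if (extreme_mode == "pad") {
    Dp <- c(rep(D[1], half), D, rep(D[n], half))
    for (i in seq_len(n)) {
      w <- Dp[i:(i + window - 1L)]
      wm[i] <- mean(w); ws[i] <- stats::sd(w)
    }
  } else {
    center <- pmin(pmax(seq_len(n), half + 1L), n - half)
    for (c0 in unique(center)) {
      w <- D[(c0 - half):(c0 + half)]
      idx <- center == c0
      wm[idx] <- mean(w); ws[idx] <- stats::sd(w)
    }
  }
  list(mean = wm, sd = ws)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment (delegates to [stats::p.adjust()]):
#' order-preserving, q in [0, 1], monotone nondecreasing in p-rank.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")
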