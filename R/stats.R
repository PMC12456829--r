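#' @title Paired contrasts, FDR control, rank correlation
#' @name stats_module
#' @description
#' Condition effects are assessed by paired t-tests across matched run
#' ensembles (run r of a stimulation condition is paired with run r of the
#' Without condition), with Benjamini-Hochberg false-discovery-rate control
#' across the edge family. FC values are Fisher z-transformed before
#' testing to stabilize the variance of bounded correlations. Rank
#' associations use Spearman correlation with average-rank ties and a
#' t-approximation for the p-value.
NULL

#' Paired t-test
#'
#' Two-sided t on the paired differences with n - 1 degrees of freedom.
#' Zero-variance differences are flagged: all-zero differences give t = 0,
#' p = 1; constant nonzero differences give a signed infinite t with p = 0
#' and `degenerate = TRUE`.
#'
#' @param a,b Equal-length numeric vectors (n >= 2), paired by index.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  n <- length(a)
  if (n < 2) abort("paired t-test needs at least 2 pairs")
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    m <- mean(d)
    if (m == 0) return(list(t = 0, p = 1, df = n - 1, degenerate = FALSE))
    return(list(t = sign(m) * Inf, p = 0, df = n - 1, degenerate = TRUE))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1), df = n - 1, degenerate = FALSE)
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up FDR control at level `q`: reject all p-values at or below the
#' largest p_(k) with p_(k) <= k q / m. Implemented through
#' `p.adjust(..., "BH")`, whose adjusted values are at or below `q` exactly
#' for the step-up rejections.
#'
#' @param pvals Vector of p-values in \[0, 1\] (NA allowed, never rejected).
#' @param q FDR level (default 0.05).
#' @return Logical mask of rejections.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    abort("p-values must lie in [0, 1]")
  adj <- p.adjust(pvals, method = "BH")
  out <- !is.na(adj) & adj <= q
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling; the p-value uses the
#' t-approximation t = rho sqrt((n-2)/(1-rho^2)) on n - 2 degrees of
#' freedom (p = 0 at |rho| = 1).
#'
#' @param x,y Equal-length numeric vectors, length >= 4, non-constant.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  n <- length(x)
  if (n < 4) abort("Spearman correlation needs at least 4 observations")
  if (sd(x) == 0 || sd(y) == 0)
    abort("Spearman correlation is undefined for constant input")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) return(list(rho = sign(rho), p = 0, n = n))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), n - 2), n = n)
}

#' Edgewise paired contrast between run ensembles
#'
#' Fisher z-transforms FC values, runs a paired t-test per off-diagonal
#' edge across matched runs, and applies BH-FDR over all edges jointly.
#' For dFC stacks, apply per window (each window is its own FDR family).
#'
#' @param cond n x n x R array of FC matrices (condition runs).
#' @param base Matched n x n x R array (baseline runs, equal R).
#' @param q FDR level (default 0.05).
#' @return A `condition_contrast`: list of n x n matrices `statistic`,
#'   `p_raw`, `rejected` (NA diagonal), plus `q_level`, `n_runs`.
#' @export
edgewise_contrast <- function(cond, base, q = 0.05) {
  if (!all(dim(cond) == dim(base)))
    abort("condition and baseline ensembles must have matching shapes")
  R <- dim(cond)[3]
  if (R < 2) abort("edgewise contrast needs at least 2 matched runs")
  n <- dim(cond)[1]
  zc <- atanh(pmin(pmax(cond, -0.999999), 0.999999))
  zb <- atanh(pmin(pmax(base, -0.999999), 0.999999))
  tmat <- matrix(NA_real_, n, n)
  pmat <- matrix(NA_real_, n, n)
  ut <- which(upper.tri(tmat), arr.ind = TRUE)
  for (e in seq_len(nrow(ut))) {
    i <- ut[e, 1]; j <- ut[e, 2]
    res <- paired_t(zc[i, j, ], zb[i, j, ])
    tmat[i, j] <- tmat[j, i] <- res$t
    pmat[i, j] <- pmat[j, i] <- res$p
  }
  pv <- pmat[upper.tri(pmat)]
  rej_ut <- bh_fdr(pv, q)
  rmat <- matrix(NA, n, n)
  rmat[upper.tri(rmat)] <- rej_ut
  rmat[lower.tri(rmat)] <- t(rmat)[lower.tri(rmat)]
  structure(list(statistic = tmat, p_raw = pmat, rejected = rmat,
                 q_level = q, n_runs = R),
            class = "condition_contrast")
}

#' @export
print.condition_contrast <- function(x, ...) {
  m <- sum(!is.na(x$p_raw[upper.tri(x$p_raw)]))
  cat(sprintf("<condition_contrast> %d edges, %d runs, %d rejected at q = %g\n",
              m, x$n_runs, sum(x$rejected, na.rm = TRUE), x$q_level))
  invisible(x)
}

#' @rdname stats_module
#' @param x A `condition_contrast`.
#' @param ... Unused.
#' @method tidy condition_contrast
#' @export
tidy.condition_contrast <- function(x, ...) {
  idx <- which(upper.tri(x$statistic), arr.ind = TRUE)
  tibble::tibble(edge_i = idx[, 1] - 1L, edge_j = idx[, 2] - 1L,
                 t = x$statistic[idx], p = x$p_raw[idx],
                 rejected = x$rejected[idx])
}

#' @rdname stats_module
#' @method glance condition_contrast
#' @export
glance.condition_contrast <- function(x, ...) {
  tb <- tidy(x)
  tibble::tibble(n_edges = nrow(tb), n_rejected = sum(tb$rejected),
                 n_runs = x$n_runs, q_level = x$q_level)
}
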