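#' @title Complexity and flexibility metrics
#' @name complexity
#' @description
#' Regional BOLD complexity is quantified three ways: the Hurst exponent
#' (long-range temporal dependence; detrended fluctuation analysis by
#' default), normalized Lempel-Ziv complexity (algorithmic richness of the
#' median-binarized series), and permutation fuzzy entropy (entropy of the
#' ordinal-pattern distribution with fuzzy down-weighting of near-tied,
#' ambiguous patterns). All three are invariant to affine rescaling of the
#' signal (the fuzzy width scales with the SD) and equivariant under region
#' permutation.
NULL

#' Hurst exponent
#'
#' Default estimator is first-order detrended fluctuation analysis: the
#' series is integrated, split into non-overlapping segments at
#' log-spaced scales from 4 to N/4, linearly detrended per segment, and
#' the slope of log RMS fluctuation against log scale is returned (0.5 for
#' white noise, about 1.5 for its cumulative sum). `method = "rs"` uses
#' rescaled-range analysis instead.
#'
#' @param series Numeric series, length >= 64, non-constant.
#' @param method `"dfa"` (default) or `"rs"`.
#' @return Scalar exponent estimate.
#' @export
hurst_exponent <- function(series, method = c("dfa", "rs")) {
  method <- match.arg(method)
  n <- length(series)
  if (n < 64) abort("Hurst estimation needs at least 64 samples")
  if (sd(series) == 0) abort("Hurst exponent is undefined for a constant series")
  if (method == "rs") return(unname(pracma::hurstexp(series, display = FALSE)$Hs))
  y <- cumsum(series - mean(series))
  scales <- unique(round(exp(seq(log(4), log(n / 4), length.out = 12))))
  f <- vapply(scales, function(s) {
    nseg <- floor(n / s)
    res2 <- vapply(seq_len(nseg), function(k) {
      seg <- y[((k - 1) * s + 1):(k * s)]
      t <- seq_len(s)
      fit <- stats::lm.fit(cbind(1, t), seg)
      mean(fit$residuals^2)
    }, numeric(1))
    sqrt(mean(res2))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(f) ~ log(scales)))[2])
}

#' Normalized Lempel-Ziv complexity
#'
#' Binarizes the series at its median (above-median = 1), counts LZ76
#' phrases c(n) by exhaustive-history parsing, and normalizes as
#' c(n) log2(n) / n, which approaches 1 for fair-coin sequences.
#'
#' @param series Numeric series, length >= 16.
#' @return Normalized complexity (>= 0).
#' @export
lempel_ziv <- function(series) {
  n <- length(series)
  if (n < 16) abort("Lempel-Ziv complexity needs at least 16 samples")
  s <- as.integer(series > median(series))
  lz76_cpp(s) * log2(n) / n
}

#' Permutation fuzzy entropy
#'
#' Each length-m embedded vector (delay `delay`) is assigned its ordinal
#' pattern; the occurrence is weighted by a fuzzy membership
#' \eqn{\prod (1 - \exp(-(\Delta/r)^{power}))} over the gaps
#' \eqn{\Delta} between consecutive sorted values, so near-ties (ambiguous
#' orderings) count less. The Shannon entropy of the membership-weighted
#' pattern distribution is normalized by log(m!): near 0 for a monotone
#' series, near 1 for white noise. With `r` proportional to the SD the
#' value is invariant under affine rescaling.
#'
#' @param series Numeric series, length >= 10 * m!.
#' @param m Embedding dimension (default 3).
#' @param delay Embedding delay in samples (default 1).
#' @param r Fuzzy width (default 0.15 * SD of the series).
#' @param fuzzy_power Exponent of the membership function (default 2).
#' @return Normalized entropy in \[0, 1\].
#' @export
pfen <- function(series, m = 3, delay = 1, r = 0.15 * sd(series),
                 fuzzy_power = 2) {
  n <- length(series)
  if (sd(series) == 0) abort("PFEN is undefined for a constant series")
  if (n < factorial(m) * 10)
    abort(sprintf("PFEN with m = %d needs at least %d samples", m,
                  factorial(m) * 10))
  n_emb <- n - (m - 1) * delay
  idx <- vapply(seq_len(n_emb),
                function(t) series[t + (0:(m - 1)) * delay],
                numeric(m))                        # m x n_emb
  pats <- apply(idx, 2, function(v) paste(order(v), collapse = ""))
  wts <- apply(idx, 2, function(v) {
    gaps <- diff(sort(v))
    prod(1 - exp(-(gaps / r)^fuzzy_power))
  })
  tot <- sum(wts)
  if (tot == 0) return(0)
  p <- tapply(wts, pats, sum) / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(factorial(m))
}

#' Per-period complexity report
#'
#' Computes Hurst, Lempel-Ziv and PFEN per region on each marked period's
#' TR slice. Periods shorter than `min_len` TRs raise an error rather than
#' silently degrading the estimates.
#'
#' @param bold A segmented `bold_series`.
#' @param periods Period names to analyze (default: all marked periods of
#'   at least `min_len` TRs, excluding `Pre`).
#' @param min_len Minimum slice length (default 64).
#' @return Tibble with columns `period`, `region`, `hurst`, `lzc`, `pfen`.
#' @export
complexity_report <- function(bold, periods = NULL, min_len = 64) {
  marks <- bold$period_marks
  if (is.null(marks)) abort("bold series has no period marks; run segment_periods()")
  if (is.null(periods)) {
    periods <- setdiff(names(marks), "Pre")
    periods <- periods[vapply(marks[periods], length, integer(1)) >= min_len]
  }
  parc <- bold$protocol$parcellation
  purrr::map_dfr(periods, function(nm) {
    idx <- marks[[nm]]
    if (length(idx) < min_len)
      abort(sprintf("period %s has %d TRs, below the %d-TR minimum",
                    nm, length(idx), min_len))
    purrr::map_dfr(seq_len(nrow(bold$data)), function(i) {
      x <- bold$data[i, idx]
      tibble::tibble(period = nm, region = parc$name[i],
                     hurst = hurst_exponent(x), lzc = lempel_ziv(x),
                     pfen = pfen(x))
    })
  })
}
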