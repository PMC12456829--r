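#' @title Dynamic functional connectivity and phase synchrony
#' @name dynamics_analysis
#' @description
#' Dynamic FC is computed with a sliding window (default 40 TRs, step 1
#' TR); from 1200 TRs this yields 1161 windowed correlation matrices.
#' Windows are assigned to three phases around the stimulation epoch:
#' Phase 1 windows lie fully inside the During-stimulation period, Phase 2
#' windows straddle the During-to-Post transition, Phase 3 windows lie
#' fully in the Post period. Phase synchrony is summarized by the Kuramoto
#' order parameter of band-limited regional phases: synchrony is its
#' temporal mean, metastability its standard deviation.
NULL

new_dfc <- function(windows, starts, window_len_tr, step_tr, parcellation,
                    window_phase = NULL) {
  structure(list(windows = windows, starts = starts,
                 window_len_tr = window_len_tr, step_tr = step_tr,
                 parcellation = parcellation, window_phase = window_phase),
            class = "dfc_stack")
}

#' @export
print.dfc_stack <- function(x, ...) {
  cat(sprintf("<dfc_stack> %d x %d x %d (window %d TRs, step %d)\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              x$window_len_tr, x$step_tr))
  if (!is.null(x$window_phase))
    cat("  phases:", paste(names(table(x$window_phase, useNA = "ifany")),
                           table(x$window_phase, useNA = "ifany"),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Sliding-window dynamic FC
#'
#' One FC matrix per window `[start, start + window_len_tr)`;
#' `floor((T - w)/step) + 1` windows in total. A window equal to the whole
#' series reproduces static FC.
#'
#' @param bold A `bold_series`.
#' @param window_len_tr Window length in TRs (default 40).
#' @param step_tr Step in TRs (default 1).
#' @return A `dfc_stack` with an n x n x W array.
#' @export
sliding_dfc <- function(bold, window_len_tr = 40, step_tr = 1) {
  T_b <- ncol(bold$data)
  if (window_len_tr > T_b) abort("window is longer than the series")
  starts <- seq(1L, T_b - window_len_tr + 1L, by = step_tr)
  n <- nrow(bold$data)
  arr <- array(NA_real_, c(n, n, length(starts)))
  xt <- t(bold$data)
  for (k in seq_along(starts)) {
    sl <- starts[k]:(starts[k] + window_len_tr - 1L)
    fc <- suppressWarnings(cor(xt[sl, , drop = FALSE]))
    fc[!is.finite(fc)] <- 0
    diag(fc) <- 1
    arr[, , k] <- fc
  }
  new_dfc(arr, starts, window_len_tr, step_tr, bold$protocol$parcellation)
}

#' Assign dFC windows to stimulation phases
#'
#' Windows are half-open TR ranges `[start, start + w)`. A window is
#' Phase 1 if fully inside the During period, Phase 2 if it contains both
#' During and Post TRs, Phase 3 if fully inside Post. Windows lying (even
#' partially) before stimulus onset stay unlabeled (NA).
#'
#' @param stack A `dfc_stack`.
#' @param bold The segmented `bold_series` the stack was computed from
#'   (needs `period_marks` with a During/Without window and Post).
#' @return The `dfc_stack` with `window_phase` filled in.
#' @export
phase_partition <- function(stack, bold) {
  marks <- bold$period_marks
  if (is.null(marks)) abort("bold series has no period marks; run segment_periods()")
  during <- marks$During %||% marks$Without
  post <- marks$Post
  if (is.null(during) || length(during) == 0 || is.null(post))
    abort("During and Post marks are required for phase partitioning")
  d_last <- max(during)
  d_first <- min(during)
  w <- stack$window_len_tr
  phase <- rep(NA_integer_, length(stack$starts))
  for (k in seq_along(stack$starts)) {
    lo <- stack$starts[k]
    hi <- lo + w - 1L
    if (lo < d_first) next
    if (hi <= d_last) phase[k] <- 1L
    else if (lo <= d_last) phase[k] <- 2L
    else phase[k] <- 3L
  }
  stack$window_phase <- phase
  stack
}

#' Seed dFC map ordered by structural connection strength
#'
#' Per-window FC of every non-seed region with the seed, rows sorted
#' ascending (weak to strong) by SC weight to the seed; visualizes how
#' stimulation effects propagate preferentially along strong structural
#' connections.
#'
#' @param stack A `dfc_stack`.
#' @param sc A `structural_connectome`.
#' @param seed_region 0-based seed id.
#' @return List with `map` ((n-1) x W matrix), `region_order` (0-based ids,
#'   ascending SC), `sc_weights` (matching order).
#' @export
seed_dfc_map <- function(stack, sc, seed_region) {
  n <- dim(stack$windows)[1]
  s1 <- seed_region + 1L
  others <- setdiff(seq_len(n), s1)
  wts <- unclass(sc)[others, s1]
  ord <- others[order(wts, others)]
  map <- t(vapply(seq_len(dim(stack$windows)[3]),
                  function(k) stack$windows[ord, s1, k],
                  numeric(length(ord))))
  list(map = t(map), region_order = ord - 1L, sc_weights = wts[match(ord, others)])
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Kuramoto synchrony and metastability
#'
#' Each regional series is demeaned and band-pass filtered (2nd-order
#' Butterworth, filtfilt, default 0.04-0.07 Hz, the customary slow BOLD
#' band), its instantaneous phase extracted from the analytic signal, and
#' the Kuramoto order parameter computed as
#' \eqn{R(t) = |n^{-1} \sum_j e^{i\phi_j(t)}|}. Synchrony is the mean of
#' R(t) and metastability its SD, after trimming 5% of samples at each end
#' to drop filter transients. With `by_period = TRUE`, R(t) from the full
#' series is additionally summarized within each marked period (the full
#' series supplies the cycles the band needs even when single periods are
#' short).
#'
#' @param bold A `bold_series`.
#' @param band_hz Band edges in Hz, below Nyquist.
#' @param trim Fraction trimmed at each end (default 0.05).
#' @param by_period Also summarize per period (needs period marks).
#' @return A `sync_summary`: list with `R_t` (full, untrimmed), `synchrony`,
#'   `metastability`, and optionally `per_period` (tibble).
#' @export
kuramoto <- function(bold, band_hz = c(0.04, 0.07), trim = 0.05,
                     by_period = FALSE) {
  fs <- 1 / bold$tr_s
  nyq <- fs / 2
  if (band_hz[1] <= 0 || band_hz[2] <= band_hz[1] || band_hz[2] >= nyq)
    abort("band edges must satisfy 0 < lo < hi < Nyquist")
  T_b <- ncol(bold$data)
  if (T_b < 3 / band_hz[1] / bold$tr_s)
    abort("series shorter than 3 cycles of the low band edge")
  bf <- signal::butter(2, band_hz / nyq, type = "pass")
  phases <- apply(bold$data, 1, function(x) {
    xf <- signal::filtfilt(bf, x - mean(x))
    Arg(analytic_signal(xf))
  })                                    # T x n
  R_t <- Mod(rowMeans(exp(1i * phases)))
  keep <- trim_idx(T_b, trim)
  out <- list(R_t = R_t, synchrony = mean(R_t[keep]),
              metastability = sd(R_t[keep]))
  if (by_period) {
    if (is.null(bold$period_marks)) abort("by_period needs period marks")
    out$per_period <- purrr::map_dfr(names(bold$period_marks), function(nm) {
      idx <- intersect(bold$period_marks[[nm]], keep)
      tibble::tibble(period = nm, synchrony = mean(R_t[idx]),
                     metastability = sd(R_t[idx]))
    })
  }
  structure(out, class = "sync_summary")
}

trim_idx <- function(T_b, trim) {
  k <- floor(trim * T_b)
  (k + 1L):(T_b - k)
}

#' @export
print.sync_summary <- function(x, ...) {
  cat(sprintf("<sync_summary> synchrony %.3f, metastability %.3f (%d samples)\n",
              x$synchrony, x$metastability, length(x$R_t)))
  invisible(x)
}

#' @rdname dynamics_analysis
#' @param x A `dfc_stack`.
#' @param ... Unused.
#' @method tidy dfc_stack
#' @export
tidy.dfc_stack <- function(x, ...) {
  W <- dim(x$windows)[3]
  n <- dim(x$windows)[1]
  off <- upper.tri(matrix(0, n, n))
  tibble::tibble(
    window = seq_len(W),
    start_tr = x$starts,
    phase = x$window_phase %||% rep(NA_integer_, W),
    mean_fc = vapply(seq_len(W), function(k) mean(x$windows[, , k][off]),
                     numeric(1))
  )
}
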