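#' @title Hemodynamics: from gating activity to BOLD
#' @name hemodynamics
#' @description
#' Regional neural activity is converted to BOLD through the
#' Balloon-Windkessel model: per region, a vasodilatory signal drives blood
#' inflow, venous volume and deoxyhemoglobin content, and the BOLD percent
#' signal is the standard nonlinear observation of volume and
#' deoxyhemoglobin. The high-rate BOLD is then post-processed the way
#' empirical acquisitions are: an initial transient is discarded and the
#' series is decimated to the scanner repetition time (TR).
NULL

#' Balloon-Windkessel parameters
#'
#' Friston (2003) constants by default.
#'
#' @param kappa Vasodilatory signal decay, 1/s (default 0.65).
#' @param gamma_f Flow-dependent feedback, 1/s (default 0.41).
#' @param tau_h Hemodynamic transit time, s (default 0.98).
#' @param alpha Grubb vessel-stiffness exponent, in (0,1) (default 0.32).
#' @param rho Resting oxygen extraction fraction (default 0.34).
#' @param V0 Resting venous blood volume fraction (default 0.02).
#' @return A `hemo_params` list.
#' @export
hemo_params <- function(kappa = 0.65, gamma_f = 0.41, tau_h = 0.98,
                        alpha = 0.32, rho = 0.34, V0 = 0.02) {
  p <- list(kappa = kappa, gamma_f = gamma_f, tau_h = tau_h, alpha = alpha,
            rho = rho, V0 = V0)
  if (any(unlist(p) <= 0)) abort("all hemodynamic parameters must be > 0")
  if (alpha >= 1) abort("alpha must be in (0, 1)")
  structure(p, class = "hemo_params")
}

#' Hemodynamic forward model
#'
#' Integrates the four-state Balloon-Windkessel ODE per region, driven by
#' the chosen neural variable of the trajectory (synaptic gating by
#' default; firing rate as an alternative). Deterministic given its inputs.
#'
#' @param traj A `neural_trajectory` sampled at 10 ms or finer.
#' @param hparams A `hemo_params` object.
#' @param drive `"gating"` (S) or `"rate"` (H).
#' @return A `bold_highres` object: n x T percent-signal matrix plus its
#'   sampling step.
#' @export
balloon_windkessel <- function(traj, hparams = hemo_params(),
                               drive = c("gating", "rate")) {
  drive <- match.arg(drive)
  if (traj$dt_rec_s > 0.010 + 1e-12)
    abort("trajectory must be sampled at 10 ms or finer for the hemodynamic stage")
  z <- if (drive == "gating") traj$S else traj$H
  bold <- balloon_windkessel_cpp(z, traj$dt_rec_s, hparams$kappa,
                                 hparams$gamma_f, hparams$tau_h,
                                 hparams$alpha, hparams$rho, hparams$V0)
  structure(list(data = bold, dt_s = traj$dt_rec_s,
                 protocol = traj$protocol),
            class = "bold_highres")
}

new_bold_series <- function(data, tr_s, t0_s, protocol, period_marks = NULL,
                            static_slice = NULL) {
  structure(list(data = data, tr_s = tr_s, t0_s = t0_s, protocol = protocol,
                 period_marks = period_marks, static_slice = static_slice),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %d regions x %d TRs (TR %.3g s, t0 %.3g s)\n",
              nrow(x$data), ncol(x$data), x$tr_s, x$t0_s))
  if (!is.null(x$period_marks))
    cat("  periods:",
        paste(sprintf("%s=%d TRs", names(x$period_marks),
                      vapply(x$period_marks, length, integer(1))),
              collapse = ", "), "\n")
  invisible(x)
}

#' Discard the transient and decimate to TR
#'
#' Drops the first `discard_s` seconds of the high-rate BOLD (initial
#' hemodynamic transient), then retains `n_points` samples spaced `tr_s`
#' apart by nearest-sample decimation (no anti-alias filter; BOLD is
#' already slow and the convention keeps indices exact). Errors, rather
#' than silently shortening, when the simulated span cannot supply
#' `n_points` samples.
#'
#' @param bold_hr A `bold_highres` object.
#' @param discard_s Seconds discarded from the start (default 60).
#' @param tr_s Repetition time, seconds (default 0.72).
#' @param n_points Retained sample count (default 1200).
#' @return A `bold_series` with `t0_s = discard_s`.
#' @export
postprocess_bold <- function(bold_hr, discard_s = 60, tr_s = 0.72,
                             n_points = 1200) {
  dt <- bold_hr$dt_s
  T_hr <- ncol(bold_hr$data)
  idx <- round((discard_s + (seq_len(n_points) - 1) * tr_s) / dt) + 1L
  if (idx[length(idx)] > T_hr)
    abort(sprintf(
      "simulated span (%.3g s) cannot supply %d points at TR %.3g s after a %.3g s discard",
      (T_hr - 1) * dt, n_points, tr_s, discard_s))
  new_bold_series(bold_hr$data[, idx, drop = FALSE], tr_s, discard_s,
                  bold_hr$protocol)
}

#' Segment a BOLD series into stimulation periods
#'
#' TR index i (0-based) covers the interval `[i*TR, (i+1)*TR)` on the
#' retained timeline (whose origin is the first retained sample). `During`
#' is the set of TRs whose full interval lies inside
#' `[onset, onset + duration]`; `Post` is everything after; TRs before
#' onset are `Pre`. For the `"Without"` protocol the same window is marked
#' `Without` so that matched-length comparisons are possible. The
#' first-130-TRs static-analysis slice is also recorded.
#'
#' @param bold A `bold_series`.
#' @param protocol A `stim_protocol`; onset is interpreted on the retained
#'   timeline (onset 0 = first retained TR).
#' @param static_trs Length of the static-analysis slice (default 130).
#' @return The `bold_series` with `period_marks` (1-based TR index vectors)
#'   and `static_slice` filled in.
#' @export
segment_periods <- function(bold, protocol = bold$protocol, static_trs = 130) {
  tr <- bold$tr_s
  T_b <- ncol(bold$data)
  onset <- protocol$onset_s
  dur <- protocol$duration_s
  if (onset < 0 || onset / tr >= T_b)
    abort("stimulus onset lies outside the retained span")
  i <- 0:(T_b - 1)
  during0 <- i[i * tr >= onset & (i + 1) * tr <= onset + dur]
  if (length(during0) > 0) {
    pre0 <- i[i < min(during0)]
    post0 <- i[i > max(during0)]
  } else {
    post0 <- i[i >= ceiling((onset + dur) / tr)]
    pre0 <- setdiff(i, post0)
  }
  marks <- list()
  if (length(pre0)) marks$Pre <- pre0 + 1L
  key <- if (protocol$label == "Without") "Without" else "During"
  marks[[key]] <- during0 + 1L
  marks$Post <- post0 + 1L
  bold$period_marks <- marks
  bold$static_slice <- seq_len(min(static_trs, T_b))
  bold
}

#' @rdname hemodynamics
#' @param x A `bold_series`.
#' @param ... Unused.
#' @method tidy bold_series
#' @export
tidy.bold_series <- function(x, ...) {
  parc <- x$protocol$parcellation
  n <- nrow(x$data)
  T_b <- ncol(x$data)
  out <- tibble::tibble(
    region = rep(parc$name, times = T_b),
    tr = rep(seq_len(T_b), each = n),
    time_s = rep(x$t0_s + (seq_len(T_b) - 1) * x$tr_s, each = n),
    bold = as.numeric(x$data)
  )
  if (!is.null(x$period_marks)) {
    period <- rep(NA_character_, T_b)
    for (nm in names(x$period_marks)) period[x$period_marks[[nm]]] <- nm
    out$period <- period[out$tr]
  }
  out
}

#' Write a BOLD series and its sidecar
#'
#' Tab-delimited matrix (rows = regions, columns = TRs) plus a `.json`
#' sidecar with TR, origin and period marks.
#'
#' @param bold A `bold_series`.
#' @param path Output path for the matrix; sidecar at `<path>.json`.
#' @export
write_bold <- function(bold, path) {
  lines <- apply(bold$data, 1L,
                 function(r) paste(sprintf("%.10g", r), collapse = "\t"))
  writeLines(lines, path)
  jsonlite::write_json(
    list(tr_s = bold$tr_s, t0_s = bold$t0_s, label = bold$protocol$label,
         period_marks = bold$period_marks, static_slice = bold$static_slice),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
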