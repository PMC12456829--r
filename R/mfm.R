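#' @title Dynamic mean-field model
#' @name mfm
#' @description
#' Each cortical region is a reduced Wong-Wang neural mass: a single NMDA
#' synaptic-gating variable \eqn{S_i \in [0,1]} with
#' \deqn{\dot S_i = -S_i/\tau_S + \gamma (1 - S_i) H(x_i) + \sigma v_i(t) + \theta_i(t)}
#' \deqn{x_i = w J S_i + G J \sum_j C_{ij} S_j + I}
#' \deqn{H(x) = (a x - b) / (1 - \exp(-d (a x - b)))}
#' where \eqn{H} is the population firing rate (Hz), \eqn{x} the total input
#' current (nA), \eqn{C} the scaled structural connectome, and
#' \eqn{\theta_i(t)} the boxcar stimulation term of the protocol. Time is in
#' seconds and rates in Hz, under which the kinetic prefactor is
#' \eqn{\gamma = 0.641} (the familiar 0.641/1000 appears only when time is
#' counted in milliseconds). Integration is Euler-Maruyama with the gating
#' state clamped to \[0, 1\].
NULL

#' Mean-field model parameters
#'
#' Canonical reduced Wong-Wang parameterization; a single homogeneous set is
#' applied to all regions.
#'
#' @param a Transfer gain slope, n/C (default 270).
#' @param b Transfer threshold, Hz (default 108).
#' @param d Transfer curvature, s (default 0.154).
#' @param tau_s Gating time constant, s (default 0.1).
#' @param gamma_kin Kinetic rate prefactor (default 0.641; dimensionless
#'   with rates in Hz and time in s).
#' @param sigma_noise Noise amplitude (default 0.01).
#' @param w Local recurrent weight (default 0.9).
#' @param J Synaptic coupling, nA (default 0.2609).
#' @param G Global coupling, dimensionless; normally fitted to data
#'   (default 2, a typical value for connectomes scaled to max 0.2).
#' @param I_ext Background input current, nA (default 0.3).
#' @return An `mfm_params` list.
#' @export
mfm_params <- function(a = 270, b = 108, d = 0.154, tau_s = 0.1,
                       gamma_kin = 0.641, sigma_noise = 0.01, w = 0.9,
                       J = 0.2609, G = 2, I_ext = 0.3) {
  p <- list(a = a, b = b, d = d, tau_s = tau_s, gamma_kin = gamma_kin,
            sigma_noise = sigma_noise, w = w, J = J, G = G, I_ext = I_ext)
  pos <- setdiff(names(p), c("I_ext", "sigma_noise"))
  if (any(unlist(p[pos]) <= 0))
    abort("all mean-field parameters except I_ext and sigma_noise must be > 0")
  if (p$I_ext < 0 || p$sigma_noise < 0)
    abort("I_ext and sigma_noise must be >= 0")
  structure(p, class = "mfm_params")
}

#' Simulation configuration
#'
#' @param dt_s Integration step, seconds (default 1e-4).
#' @param total_s Simulated span, seconds.
#' @param seed Integer seed for the noise stream.
#' @param record_every Steps between stored samples (default 10, i.e. 1 ms
#'   at the default step).
#' @return A `sim_config` list.
#' @export
sim_config <- function(total_s, dt_s = 1e-4, seed = 1, record_every = 10L) {
  if (dt_s <= 0) abort("dt_s must be > 0")
  if (total_s < dt_s) abort("total_s must be >= dt_s")
  if (record_every < 1) abort("record_every must be >= 1")
  structure(list(dt_s = dt_s, total_s = total_s, seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

#' Population transfer function
#'
#' \eqn{H(x) = (a x - b)/(1 - e^{-d(a x - b)})}, evaluated as \eqn{1/d} at
#' the removable singularity \eqn{a x = b}. Positive for all real inputs
#' (numerator and denominator share sign); asymptotically linear,
#' \eqn{H \to a x - b}, for large drive.
#'
#' @param x Input current, nA (vectorized).
#' @param params An `mfm_params` object.
#' @return Firing rate(s), Hz.
#' @export
transfer_rate <- function(x, params = mfm_params()) {
  transfer_rate_cpp(as.numeric(x), params$a, params$b, params$d)
}

#' Deterministic drift of the gating equations
#'
#' Returns the drift \eqn{dS/dt} together with the input currents and
#' firing rates it implies; noise is added by the stepper, not here. The
#' stimulation term enters additively, so the elementwise drift difference
#' between theta and zero-theta is exactly theta.
#'
#' @param S Length-n gating state.
#' @param sc A `structural_connectome` (scaled).
#' @param params An `mfm_params` object.
#' @param theta Length-n stimulation term (default all zero).
#' @return List with `dS`, `x`, `H`.
#' @export
mfm_drift <- function(S, sc, params = mfm_params(), theta = numeric(length(S))) {
  n <- nrow(sc)
  if (length(S) != n || length(theta) != n)
    abort("S and theta must have one entry per region")
  x <- params$w * params$J * S +
    params$G * params$J * as.numeric(unclass(sc) %*% S) + params$I_ext
  H <- transfer_rate(x, params)
  dS <- -S / params$tau_s + params$gamma_kin * (1 - S) * H + theta
  list(dS = dS, x = x, H = H)
}

#' Simulate the coupled mean-field model
#'
#' Euler-Maruyama: \eqn{S(t+dt) = clamp_{[0,1]}(S + drift \cdot dt + \sigma
#' \sqrt{dt}\, \xi)} with iid standard-normal \eqn{\xi} per region per step.
#' The stimulation boxcar is applied on \eqn{[onset, onset+duration)}.
#' Identical seeds give bit-identical trajectories; with
#' `sigma_noise = 0` the scheme is deterministic and draws no random
#' numbers. Divergence (non-finite state) aborts with a diagnostic. Clamp
#' activations are counted in the result; at default noise and zero theta
#' none are expected.
#'
#' @param params An `mfm_params` object.
#' @param sc A scaled `structural_connectome`.
#' @param protocol A `stim_protocol`.
#' @param config A `sim_config`.
#' @param S0 Initial gating state (default 0.1 uniformly).
#' @return A `neural_trajectory`: list with `time_s` and n x T matrices `S`
#'   (gating), `H` (firing rate, Hz), `x` (current, nA), plus `clamp_hits`.
#' @export
simulate_mfm <- function(params, sc, protocol, config,
                         S0 = rep(0.1, nrow(sc))) {
  if (!isTRUE(attr(sc, "scaled")))
    warn("simulating with an unscaled structural connectome")
  n_steps <- round(config$total_s / config$dt_s)
  theta <- if (protocol$label == "Without") numeric(nrow(sc)) else protocol$theta
  res <- with_seed(config$seed, {
    sim_mfm_cpp(S0, unclass(sc), params$a, params$b, params$d, params$tau_s,
                params$gamma_kin, params$sigma_noise, params$w, params$J,
                params$G, params$I_ext, theta, protocol$onset_s,
                protocol$duration_s, config$dt_s, n_steps,
                config$record_every)
  })
  structure(list(time_s = res$time_s, S = res$S, H = res$H, x = res$x,
                 clamp_hits = res$clamp_hits,
                 dt_rec_s = config$dt_s * config$record_every,
                 params = params, protocol = protocol, config = config),
            class = "neural_trajectory")
}

#' @export
print.neural_trajectory <- function(x, ...) {
  cat(sprintf("<neural_trajectory> %d regions x %d samples (%.3g s at %g ms), protocol '%s', clamp hits %d\n",
              nrow(x$S), ncol(x$S), max(x$time_s), 1000 * x$dt_rec_s,
              x$protocol$label, x$clamp_hits))
  invisible(x)
}

#' Find a deterministic fixed point of the gating dynamics
#'
#' Damped fixed-point iteration on drift = 0 with zero noise and zero
#' stimulation; used for initialization and for equilibrium checks.
#'
#' @param params An `mfm_params` object.
#' @param sc A scaled `structural_connectome`.
#' @param S0 Starting state.
#' @param tol Convergence tolerance on max |dS|.
#' @param max_iter Iteration budget.
#' @return Length-n fixed-point gating state.
#' @export
mfm_fixed_point <- function(params, sc, S0 = rep(0.05, nrow(sc)),
                            tol = 1e-12, max_iter = 20000L) {
  S <- S0
  for (i in seq_len(max_iter)) {
    dr <- mfm_drift(S, sc, params)
    S <- pmin(1, pmax(0, S + 0.02 * dr$dS))
    if (max(abs(dr$dS)) < tol) return(S)
  }
  warn("fixed-point iteration did not fully converge")
  S
}

#' @rdname mfm
#' @param x A `neural_trajectory`.
#' @param ... Unused.
#' @method tidy neural_trajectory
#' @export
tidy.neural_trajectory <- function(x, ...) {
  parc <- x$protocol$parcellation
  n <- nrow(x$S)
  tibble::tibble(
    region = rep(parc$name, times = ncol(x$S)),
    time_s = rep(x$time_s, each = n),
    gating = as.numeric(x$S),
    rate_hz = as.numeric(x$H)
  )
}
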