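p <- mfm_params()

test_that("transfer function handles the removable singularity and asymptote", {
  # L'Hopital limit at a x = b is 1/d, continuous through the singularity
  x0 <- p$b / p$a
  expect_equal(transfer_rate(x0, p), 1 / p$d)
  expect_equal(transfer_rate(x0 + 1e-9, p), 1 / p$d, tolerance = 1e-6)
  expect_equal(transfer_rate(x0 - 1e-9, p), 1 / p$d, tolerance = 1e-6)

  # direct evaluation at the background current
  u <- p$a * 0.3 - p$b
  expect_equal(transfer_rate(0.3, p), u / (1 - exp(-p$d * u)))
  expect_gt(transfer_rate(0.3, p), 0)

  # linear asymptote for strong drive
  xl <- (p$b + 25 / p$d) / p$a
  expect_equal(transfer_rate(xl, p), p$a * xl - p$b, tolerance = 1e-6)
})

test_that("drift matches the gating equations and theta enters additively", {
  sc <- synthetic_sc(8, density = 0.6, seed = 3)
  # S = 0 removes recurrence and coupling: dS = gamma * H(I)
  d0 <- mfm_drift(rep(0, 8), sc, p)
  expect_equal(d0$dS, rep(p$gamma_kin * transfer_rate(p$I_ext, p), 8))
  expect_equal(d0$x, rep(p$I_ext, 8))

  # drift difference under theta is exactly theta
  S <- seq(0.05, 0.4, length.out = 8)
  th <- c(1, -1, rep(0, 6)) * 0.5
  expect_equal(mfm_drift(S, sc, p, th)$dS - mfm_drift(S, sc, p)$dS, th)

  # S = 1 with the firing term nulled leaves pure decay plus theta
  d1 <- mfm_drift(rep(1, 8), sc, p, th)
  expect_equal(d1$dS, -rep(1 / p$tau_s, 8) + p$gamma_kin * 0 *
                 transfer_rate(d1$x, p) + th)
  expect_error(mfm_drift(rep(0.1, 5), sc, p), "entry per region")
})

test_that("integration is reproducible and deterministic without noise", {
  sc <- synthetic_sc(6, density = 0.6, seed = 2)
  proto <- without_protocol(attr(sc, "parcellation"))
  cfg <- sim_config(total_s = 2, seed = 99)
  t1 <- simulate_mfm(p, sc, proto, cfg)
  t2 <- simulate_mfm(p, sc, proto, cfg)
  expect_identical(t1$S, t2$S)

  p0 <- mfm_params(sigma_noise = 0)
  a <- simulate_mfm(p0, sc, proto, sim_config(total_s = 1, seed = 1))
  b <- simulate_mfm(p0, sc, proto, sim_config(total_s = 1, seed = 2))
  expect_identical(a$S, b$S)
})

test_that("a deterministic fixed point is preserved by the integrator", {
  sc <- synthetic_sc(6, density = 0.6, seed = 4)
  p0 <- mfm_params(sigma_noise = 0)
  S_star <- mfm_fixed_point(p0, sc)
  expect_lt(max(abs(mfm_drift(S_star, sc, p0)$dS)), 1e-10)
  proto <- without_protocol(attr(sc, "parcellation"))
  traj <- simulate_mfm(p0, sc, proto, sim_config(total_s = 10, seed = 1),
                       S0 = S_star)
  expect_lt(max(abs(traj$S - S_star)), 1e-6)
  expect_equal(traj$clamp_hits, 0)
})

test_that("stimulation shifts the stimulated region monotonically by sign", {
  sc <- synthetic_sc(6, density = 0.6, seed = 5)
  parc <- attr(sc, "parcellation")
  p0 <- mfm_params(sigma_noise = 0)
  mk <- function(th1) {
    pr <- without_protocol(parc, onset_s = 0, duration_s = 10)
    pr$label <- "stim"
    pr$theta <- c(th1, rep(0, 5))
    pr
  }
  cfg <- sim_config(total_s = 10, seed = 1)
  base <- simulate_mfm(p0, sc, mk(0), cfg)
  up <- simulate_mfm(p0, sc, mk(0.5), cfg)
  dn <- simulate_mfm(p0, sc, mk(-0.5), cfg)
  last <- ncol(base$S)
  expect_gt(up$S[1, last], base$S[1, last])
  expect_lt(dn$S[1, last], base$S[1, last])
  expect_gt(mean(up$H[1, ]), mean(base$H[1, ]))
  expect_lt(mean(dn$H[1, ]), mean(base$H[1, ]))
})

test_that("small-theta steady-state response is linear within 5 percent", {
  sc <- synthetic_sc(6, density = 0.6, seed = 6)
  parc <- attr(sc, "parcellation")
  p0 <- mfm_params(sigma_noise = 0)
  S_star <- mfm_fixed_point(p0, sc)
  resp <- function(th1) {
    pr <- without_protocol(parc, onset_s = 0, duration_s = 20)
    pr$label <- "stim"; pr$theta <- c(th1, rep(0, 5))
    traj <- simulate_mfm(p0, sc, pr, sim_config(total_s = 20, seed = 1),
                         S0 = S_star)
    traj$S[1, ncol(traj$S)] - S_star[1]
  }
  r1 <- resp(0.005)
  r2 <- resp(0.010)
  expect_equal(r2 / r1, 2, tolerance = 0.05)
})

test_that("halving the step changes the noiseless trajectory at first order", {
  sc <- synthetic_sc(4, density = 0.9, seed = 7)
  proto <- without_protocol(attr(sc, "parcellation"))
  p0 <- mfm_params(sigma_noise = 0)
  run_dt <- function(dt) {
    simulate_mfm(p0, sc, proto,
                 sim_config(total_s = 2, dt_s = dt, seed = 1,
                            record_every = round(0.01 / dt)))$S
  }
  S1 <- run_dt(1e-3)
  S2 <- run_dt(5e-4)
  S4 <- run_dt(2.5e-4)
  e12 <- max(abs(S1 - S2))
  e24 <- max(abs(S2 - S4))
  expect_lt(e12, 1e-3)
  expect_lt(e24, e12)          # error shrinks with the step
})

test_that("clamping stays inactive at baseline noise without stimulation", {
  sc <- synthetic_sc(8, density = 0.5, seed = 8)
  proto <- without_protocol(attr(sc, "parcellation"))
  traj <- simulate_mfm(p, sc, proto, sim_config(total_s = 5, seed = 12))
  expect_equal(traj$clamp_hits, 0)
  expect_true(all(traj$S >= 0 & traj$S <= 1))
})
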