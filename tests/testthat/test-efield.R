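parc16 <- synthetic_parcellation(16)

test_that("e-field reading validates region ids and round-trips", {
  ef <- synthetic_efield(parc16, 4, 12, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_efield(ef, tmp)
  back <- read_efield(tmp, parc16)
  expect_equal(back$e_normal, ef$e_normal)
  expect_equal(nrow(back), 16 * 100)

  writeLines(c("region_id,e_normal_mvmm", "99,1.0"), tmp)
  expect_error(read_efield(tmp, parc16), "unknown region")
  writeLines("region_id,e_normal_mvmm", tmp)
  expect_error(read_efield(tmp, parc16), "empty")
})

test_that("percentile-peak rule selects crucial regions strictly above the peak", {
  # constant field: max == peak, strict inequality leaves the set empty
  const <- tdcsim:::validate_efield(
    tibble::tibble(region_id = rep(0:15, each = 5), e_normal = 1), parc16)
  expect_length(crucial_regions(const), 0)

  # one region holding the 20 largest of 2000 samples is found at the
  # 99th percentile; verified against a brute-force percentile comparison
  set.seed(42)
  base <- tibble::tibble(region_id = rep(0:15, length.out = 1980),
                         e_normal = rnorm(1980, 0, 0.1))
  spike <- tibble::tibble(region_id = 7L, e_normal = seq(5, 6, length.out = 20))
  samples <- tdcsim:::validate_efield(rbind(base, spike), parc16)
  got <- crucial_regions(samples, 99)
  av <- abs(samples$e_normal)
  peak <- quantile(av, 0.99, type = 7)
  brute <- sort(as.integer(names(which(tapply(av, samples$region_id, max) > peak))))
  expect_identical(got, brute)
  expect_identical(got, 7L)

  # percentile 0: every sampled region exceeds the minimum
  expect_identical(crucial_regions(samples, 0), 0:15)
})

test_that("theta follows the linear polarization law with sign preserved", {
  df <- tibble::tibble(region_id = c(0L, 1L, 2L), e_normal = c(30, -30, 0))
  samples <- tdcsim:::validate_efield(df, synthetic_parcellation(3))
  proto <- build_protocol(samples, crucial = c(0L, 1L), label = "test")
  # 0.13 * 30 = 3.9 mV, within the |4 mV| polarization bound
  expect_equal(proto$theta[1], 3.9)
  expect_equal(proto$theta[2], -3.9)
  expect_lte(max(abs(proto$theta)), 4)
  expect_equal(proto$theta[3], 0)

  # linear in lambda and k
  p2 <- build_protocol(samples, crucial = c(0L, 1L), lambda_coeff = 0.26,
                       label = "test")
  expect_equal(p2$theta, 2 * proto$theta)
  p3 <- build_protocol(samples, crucial = c(0L, 1L), k_gain = 3,
                       label = "test")
  expect_equal(p3$theta, 3 * proto$theta)

  # with k = 1 theta numerically equals the polarization V_tDCS
  expect_equal(proto$theta[1], proto$lambda_coeff * 30)
})

test_that("crucial selection is invariant under global positive rescaling", {
  ef <- synthetic_efield(parc16, 2, 9, seed = 5)
  scaled <- ef
  scaled$e_normal <- 17 * scaled$e_normal
  expect_identical(crucial_regions(ef), crucial_regions(scaled))
})

test_that("synthetic bipolar field is reproducible and recovers its foci", {
  a <- synthetic_efield(parc16, 4, 12, peak_mvmm = 1, background_sd = 0.01,
                        seed = 9)
  b <- synthetic_efield(parc16, 4, 12, peak_mvmm = 1, background_sd = 0.01,
                        seed = 9)
  expect_identical(a$e_normal, b$e_normal)
  expect_identical(crucial_regions(a), c(4L, 12L))

  z <- synthetic_efield(parc16, 0, 1, background_sd = 0, seed = 2)
  expect_true(all(z$e_normal[!z$region_id %in% c(0, 1)] == 0))
  expect_error(synthetic_efield(parc16, 3, 3, seed = 1), "must differ")
})

test_that("stimulation waveform is a half-open boxcar, zero for Without", {
  df <- tibble::tibble(region_id = 0:1, e_normal = c(10, -10))
  samples <- tdcsim:::validate_efield(df, synthetic_parcellation(2))
  proto <- build_protocol(samples, crucial = 0:1, onset_s = 5,
                          duration_s = 10, label = "x")
  expect_equal(theta_waveform(proto, 5), proto$theta)
  expect_equal(theta_waveform(proto, 14.999), proto$theta)
  expect_equal(theta_waveform(proto, 15), c(0, 0))
  expect_equal(theta_waveform(proto, 0), c(0, 0))
  wo <- without_protocol(synthetic_parcellation(2), 5, 10)
  expect_equal(theta_waveform(wo, 7), c(0, 0))
})
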