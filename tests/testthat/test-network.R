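test_that("FC reproduces hand-computable correlations and flags zero variance", {
  parc <- synthetic_parcellation(3)
  x <- c(1, 2, 4)
  data <- rbind(x, x, -x)
  b <- make_bold(data, parcellation = parc)
  fc <- bold_fc(b, 1:3)
  expect_equal(unclass(fc)[1, 2], 1)
  expect_equal(unclass(fc)[1, 3], -1)

  y <- c(1, 3, 2)
  b2 <- make_bold(rbind(x, y, y), parcellation = parc)
  fc2 <- bold_fc(b2, 1:3)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unclass(fc2)[1, 2], hand)

  flat <- make_bold(rbind(x, c(1, 1, 1), y), parcellation = parc)
  expect_warning(fcz <- bold_fc(flat, 1:3), "zero-variance")
  expect_equal(unclass(fcz)[1, 2], 0)
  expect_error(bold_fc(b, 1:2), "at least 3")
})

test_that("graph metrics reproduce closed forms and the star example", {
  ones <- matrix(1, 5, 5); diag(ones) <- 0
  gm <- graph_metrics(ones)
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$char_path_length, 1)
  expect_equal(gm$clustering_coefficient, 1)

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  gs <- graph_metrics(star)
  expect_equal(gs$global_efficiency, 0.75)   # (3*1 + 3*0.5) / 6
  expect_equal(gs$char_path_length, 1.5)
  expect_equal(gs$clustering_coefficient, 0)

  # two components: efficiency counts unreachable pairs as 0; path length
  # averages over connected pairs only
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- 1
  two[3, 4] <- two[4, 3] <- 1
  gt <- graph_metrics(two)
  expect_equal(gt$global_efficiency, 2 / 6)
  expect_equal(gt$char_path_length, 1)
})

test_that("distances and efficiency agree with a brute-force oracle on random graphs", {
  for (s in 1:5) {
    set.seed(s)
    n <- 8
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    vals <- runif(sum(ut)) * (runif(sum(ut)) < 0.4)
    w[ut] <- vals
    w <- w + t(w)
    if (all(w == 0)) next
    gm <- graph_metrics(w)
    expect_equal(gm$global_efficiency, brute_efficiency(w), tolerance = 1e-12)
    expect_equal(gm$char_path_length, brute_cpl(w), tolerance = 1e-12)
  }
})

test_that("efficiency never decreases when a single weight increases", {
  set.seed(7)
  n <- 10
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  vals <- runif(nrow(ut)) * (runif(nrow(ut)) < 0.5)
  for (e in seq_len(nrow(ut)))
    w[ut[e, 1], ut[e, 2]] <- w[ut[e, 2], ut[e, 1]] <- vals[e]
  e0 <- graph_metrics(w)$global_efficiency
  for (e in sample(which(vals > 0), 5)) {
    w2 <- w
    w2[ut[e, 1], ut[e, 2]] <- w2[ut[e, 2], ut[e, 1]] <- vals[e] * 2
    expect_gte(graph_metrics(w2)$global_efficiency, e0)
  }
})

test_that("RSN aggregation recovers block structure and ignores region order", {
  parc <- synthetic_parcellation(14)        # 7 networks x 2 regions
  n <- 14
  fcm <- matrix(0.2, n, n)
  for (lab in unique(parc$rsn)) {
    ip <- which(parc$rsn == lab)
    fcm[ip, ip] <- 0.8
  }
  diag(fcm) <- 1
  fc <- tdcsim:::new_fc(fcm, parc)
  m <- rsn_fc(fc, parc)
  expect_equal(unname(diag(m)), rep(0.8, 7))
  expect_equal(unname(m[upper.tri(m)]), rep(0.2, 21))

  perm <- sample(n)
  parc_p <- parc[perm, ]
  parc_p$id <- 0:(n - 1)                     # relabel in permuted order
  fc_p <- tdcsim:::new_fc(fcm[perm, perm], parc_p)
  expect_equal(rsn_fc(fc_p, parc_p), m)

  # constant FC aggregates to that constant everywhere
  cfc <- tdcsim:::new_fc(matrix(0.3, n, n), parc)
  expect_true(all(rsn_fc(cfc, parc) == 0.3))
})

test_that("seed split ranks by SC with deterministic tie-breaking", {
  n <- 68
  parc <- synthetic_parcellation(n)
  m <- matrix(0, n, n)
  m[1, 2:n] <- m[2:n, 1] <- 1:67           # weights 1..67 to the seed
  sc <- tdcsim:::new_connectome(m, parc, FALSE)
  fc <- tdcsim:::new_fc(diag(n), parc)
  sp <- seed_fc_split(fc, sc, seed_region = 0, top_k = 10)
  expect_identical(sp$high_sc, 58:67)       # ids of weights 58..67
  expect_length(sp$low_sc, 57)
  expect_length(sp$fc_to_seed, 67)

  sp_all <- seed_fc_split(fc, sc, 0, top_k = n - 1)
  expect_length(sp_all$low_sc, 0)

  z <- tdcsim:::new_connectome(matrix(0, 4, 4), synthetic_parcellation(4), FALSE)
  fz <- tdcsim:::new_fc(diag(4), synthetic_parcellation(4))
  expect_warning(seed_fc_split(fz, z, 0, top_k = 2), "degenerate")
})

test_that("SC-to-BOLD rank correlation behaves at the extremes", {
  n <- 60
  parc <- synthetic_parcellation(n)
  set.seed(3)
  m <- matrix(0, n, n)
  wts <- runif(n - 1)
  m[1, 2:n] <- m[2:n, 1] <- wts
  sc <- tdcsim:::new_connectome(m, parc, FALSE)
  tv <- numeric(n)
  tv[2:n] <- 2 * wts + 1                    # t strictly increasing in SC
  res <- sc_bold_correlation(sc, tv, seed_region = 0, sc_sparsity = 0.5)
  expect_equal(res$rho, 1)

  # independent t-values: negligible association
  set.seed(11)
  rhos <- replicate(20, {
    tvp <- numeric(n); tvp[2:n] <- rnorm(n - 1)
    sc_bold_correlation(sc, tvp, 0, sc_sparsity = 0.5)$rho
  })
  expect_lt(abs(mean(rhos)), 0.2)

  expect_error(sc_bold_correlation(sc, tv, 0, sc_sparsity = 0.01), "fewer than 4")
})
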