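test_that("parcellation reading validates structure and atlas size is free", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  parc68 <- synthetic_parcellation(68)
  readr::write_csv(tibble::as_tibble(parc68), tmp)
  got <- read_parcellation(tmp)
  expect_equal(nrow(got), 68)
  expect_setequal(unique(got$rsn), c("FPN", "DMN", "LIM", "DAN", "VAN",
                                     "SMN", "VIS"))

  parc148 <- synthetic_parcellation(148)
  readr::write_csv(tibble::as_tibble(parc148), tmp)
  expect_equal(nrow(read_parcellation(tmp)), 148)

  bad <- tibble::as_tibble(parc68)
  bad$name[2] <- bad$name[1]
  readr::write_csv(bad, tmp)
  expect_error(read_parcellation(tmp), "duplicate")

  bad2 <- tibble::as_tibble(parc68)
  bad2$rsn[1] <- "NOPE"
  readr::write_csv(bad2, tmp)
  expect_error(read_parcellation(tmp), "RSN")

  readr::write_csv(tibble::as_tibble(parc68)[1, ], tmp)
  expect_error(read_parcellation(tmp), "at least 2")
})

test_that("SC reading symmetrizes tiny asymmetry, rejects bad matrices, and round-trips", {
  parc <- synthetic_parcellation(6)
  sc <- synthetic_sc(6, density = 0.8, seed = 7, parcellation = parc)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_sc(sc, tmp)
  back <- read_sc(tmp, parc)
  bare <- function(x) matrix(as.numeric(x), nrow(x))
  expect_identical(bare(back), bare(sc))

  m <- unclass(sc)
  m[1, 2] <- m[1, 2] + 1e-12          # tiny asymmetry: silently repaired
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t")), tmp)
  rep <- read_sc(tmp, parc)
  expect_equal(unclass(rep)[1, 2], unclass(rep)[2, 1])

  m2 <- unclass(sc); m2[1, 2] <- m2[1, 2] + 0.5   # gross asymmetry: error
  writeLines(apply(m2, 1, function(r) paste(sprintf("%.17g", r),
                                            collapse = "\t")), tmp)
  expect_error(read_sc(tmp, parc), "asymmetry")

  m3 <- unclass(sc); m3[1, 2] <- m3[2, 1] <- -1
  writeLines(apply(m3, 1, function(r) paste(sprintf("%.17g", r),
                                            collapse = "\t")), tmp)
  expect_error(read_sc(tmp, parc), "negative")

  expect_error(read_sc(tmp, synthetic_parcellation(5)), "match|square")
})

test_that("consensus keeps edges by presence fraction with cross-subject means", {
  parc <- synthetic_parcellation(3)
  mk <- function(w12, w13 = 0, w23 = 0) {
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- w12
    m[1, 3] <- m[3, 1] <- w13
    m[2, 3] <- m[3, 2] <- w23
    tdcsim:::new_connectome(m, parc, scaled = FALSE)
  }
  # edge (1,2) present in 2 of 5 subjects -> dropped at fraction 0.5
  subs <- list(mk(1), mk(2), mk(0), mk(0), mk(0))
  cons <- consensus_sc(subs, 0.5)
  expect_equal(unclass(cons)[1, 2], 0)
  # present in all with weights 1, 2, 3 -> arithmetic mean 2
  subs2 <- list(mk(1), mk(2), mk(3))
  expect_equal(unclass(consensus_sc(subs2, 0.5))[1, 2], 2)
  # single subject is its own consensus
  expect_equal(unclass(consensus_sc(list(mk(5)), 0.5)), unclass(mk(5)))
  expect_error(consensus_sc(list(mk(1),
                                 tdcsim:::new_connectome(matrix(0, 2, 2),
                                                         synthetic_parcellation(2),
                                                         FALSE))),
               "mismatch")
})

test_that("consensus at vanishing presence equals the mean over edges seen anywhere", {
  parc <- synthetic_parcellation(5)
  subs <- lapply(1:4, function(s) {
    m <- unclass(synthetic_sc(5, density = 0.5, seed = s,
                              parcellation = parc))
    tdcsim:::new_connectome(m, parc, FALSE)
  })
  cons <- consensus_sc(subs, presence_fraction = 1e-9)
  # brute-force oracle over every edge
  for (i in 1:4) for (j in (i + 1):5) {
    vals <- vapply(subs, function(s) unclass(s)[i, j], numeric(1))
    expected <- if (any(vals != 0)) mean(vals) else 0
    expect_equal(unclass(cons)[i, j], expected)
  }
})

test_that("scaling fixes the maximum element at 0.2 exactly and is idempotent", {
  parc <- synthetic_parcellation(4)
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 5
  m[3, 4] <- m[4, 3] <- 1
  sc <- tdcsim:::new_connectome(m, parc, FALSE)
  sc2 <- scale_sc(sc)
  expect_identical(max(sc2), 0.2)
  expect_equal(unclass(sc2)[3, 4], 1 * 0.2 / 5)
  expect_identical(unclass(scale_sc(sc2)), unclass(sc2))
  expect_true(attr(sc2, "scaled"))
  expect_error(scale_sc(tdcsim:::new_connectome(matrix(0, 4, 4), parc, FALSE)),
               "all-zero")
})

test_that("synthetic SC is reproducible, symmetric, connected, scaled", {
  a <- synthetic_sc(68, density = 0.3, seed = 11)
  b <- synthetic_sc(68, density = 0.3, seed = 11)
  expect_identical(unclass(a), unclass(b))
  expect_identical(unclass(a), t(unclass(a)))
  expect_identical(max(a), 0.2)
  expect_equal(diag(unclass(a)), rep(0, 68))
  g <- igraph::graph_from_adjacency_matrix(unclass(a) > 0, mode = "undirected")
  expect_true(igraph::is_connected(g))
  # n = 2 forces the single edge at the scaled maximum
  two <- synthetic_sc(2, density = 0.5, seed = 1)
  expect_identical(unclass(two)[1, 2], 0.2)
})
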