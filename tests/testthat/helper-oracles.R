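# Independent brute-force oracles used to cross-check the implementation.

# LZ76 phrase count by explicit exhaustive-history parsing: walk the
# sequence, extending the current phrase until it is not a substring of the
# history followed by the phrase-so-far minus its last symbol.
brute_lz76 <- function(s) {
  n <- length(s)
  c_n <- 0L
  i <- 1L
  while (i <= n) {
    k <- 1L
    repeat {
      if (i + k - 1L > n) break
      phrase <- s[i:(i + k - 1L)]
      hist <- s[seq_len(i + k - 2L)]
      found <- FALSE
      if (length(hist) >= k) {
        for (st in 1:(length(hist) - k + 1L)) {
          if (all(hist[st:(st + k - 1L)] == phrase)) { found <- TRUE; break }
        }
      }
      if (!found) break
      k <- k + 1L
    }
    c_n <- c_n + 1L
    i <- i + k
  }
  c_n
}

# All-pairs shortest paths by Floyd-Warshall on edge lengths 1/weight.
brute_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

brute_efficiency <- function(w) {
  d <- brute_distances(w)
  pairs <- d[upper.tri(d)]
  mean(ifelse(is.finite(pairs), 1 / pairs, 0))
}

brute_cpl <- function(w) {
  d <- brute_distances(w)
  pairs <- d[upper.tri(d)]
  mean(pairs[is.finite(pairs)])
}

# Benjamini-Hochberg step-up performed literally from its definition.
brute_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(ks) > 0) rej[ord[seq_len(max(ks))]] <- TRUE
  rej
}

# Minimal BOLD container around an arbitrary matrix, for analysis-stage
# tests that do not need a simulation behind them.
make_bold <- function(data, tr_s = 0.72, parcellation = NULL,
                      label = "Without", onset_s = 0, duration_s = 60) {
  n <- nrow(data)
  if (is.null(parcellation)) parcellation <- synthetic_parcellation(max(n, 2))
  proto <- if (label == "Without") {
    without_protocol(parcellation, onset_s, duration_s)
  } else {
    p <- without_protocol(parcellation, onset_s, duration_s)
    p$label <- label
    p
  }
  tdcsim:::new_bold_series(data, tr_s, 0, proto)
}

make_bold_highres <- function(data, dt_s, parcellation = NULL) {
  n <- nrow(data)
  if (is.null(parcellation)) parcellation <- synthetic_parcellation(max(n, 2))
  structure(list(data = data, dt_s = dt_s,
                 protocol = without_protocol(parcellation)),
            class = "bold_highres")
}
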