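#' @title Static functional connectivity and graph topology
#' @name network_analysis
#' @description
#' Functional connectivity (FC) is the Pearson correlation between regional
#' BOLD time courses. Graph metrics summarize the FC matrix as a weighted
#' network: global efficiency (integration), mean clustering coefficient
#' (segregation, Onnela weighted form), and characteristic path length.
#' Negative correlations are zeroed before graph construction and edge
#' weights are turned into distances as 1/w, so stronger coupling means
#' shorter paths. FC is also aggregated within and between resting-state
#' networks, and seed-based analyses split regions by the strength of their
#' structural connection to a stimulated seed.
NULL

new_fc <- function(values, parcellation, window = NULL) {
  dimnames(values) <- NULL
  structure(values, parcellation = parcellation, window = window,
            class = c("fc_matrix", "matrix", "array"))
}

#' Functional-connectivity matrix
#'
#' Pairwise Pearson correlation of regional BOLD over a TR slice. A
#' zero-variance region yields undefined correlations; these are recorded
#' as 0 with a warning.
#'
#' @param bold A `bold_series`.
#' @param slice 1-based TR indices (default: the stored static-analysis
#'   slice, else all TRs). At least 3 TRs.
#' @return An `fc_matrix`: symmetric, unit diagonal, entries in \[-1, 1\].
#' @export
bold_fc <- function(bold, slice = NULL) {
  if (is.null(slice)) slice <- bold$static_slice %||% seq_len(ncol(bold$data))
  if (length(slice) < 3) abort("FC needs a slice of at least 3 TRs")
  x <- t(bold$data[, slice, drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warn("zero-variance region(s) in FC slice; correlations recorded as 0")
    fc <- suppressWarnings(cor(x))
    fc[!is.finite(fc)] <- 0
    diag(fc) <- 1
  } else {
    fc <- cor(x)
  }
  new_fc(fc, bold$protocol$parcellation,
         window = c(min(slice), max(slice)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted graph topology metrics
#'
#' Builds a weighted graph from an FC matrix (negative entries zeroed,
#' diagonal dropped; optionally only the strongest `sparsity` fraction of
#' edges retained) and computes:
#' \itemize{
#' \item global efficiency: mean of 1/d over all distinct pairs
#'   (disconnected pairs contribute 0), distances from shortest paths with
#'   edge length 1/weight;
#' \item characteristic path length: mean shortest-path distance over
#'   connected pairs only;
#' \item clustering coefficient: mean Onnela weighted clustering (weights
#'   rescaled by the maximum; nodes with degree < 2 contribute 0).
#' }
#'
#' @param fc An `fc_matrix` (or plain symmetric matrix).
#' @param scheme `"weighted"` (default) or `"proportional_threshold"`.
#' @param sparsity Fraction of strongest edges retained when thresholding.
#' @return One-row tibble with `global_efficiency`,
#'   `clustering_coefficient`, `char_path_length`.
#' @export
graph_metrics <- function(fc, scheme = c("weighted", "proportional_threshold"),
                          sparsity = NULL) {
  scheme <- match.arg(scheme)
  w <- unclass(fc)
  w[w < 0] <- 0
  diag(w) <- 0
  if (scheme == "proportional_threshold") {
    if (is.null(sparsity) || sparsity <= 0 || sparsity > 1)
      abort("proportional thresholding needs sparsity in (0, 1]")
    ut <- w[upper.tri(w)]
    pos <- ut[ut > 0]
    if (length(pos) == 0) abort("graph is empty after thresholding")
    cut <- quantile(pos, 1 - sparsity, type = 7)
    w[w < cut] <- 0
  }
  if (all(w == 0)) abort("graph has no edges")
  d <- graph_distances(w)
  n <- nrow(w)
  pairs <- d[upper.tri(d)]
  eff <- mean(ifelse(is.finite(pairs), 1 / pairs, 0))
  conn <- pairs[is.finite(pairs)]
  cpl <- if (length(conn) > 0) mean(conn) else NA_real_
  tibble::tibble(global_efficiency = eff,
                 clustering_coefficient = onnela_clustering(w),
                 char_path_length = cpl)
}

# All-pairs shortest-path distances with edge length 1/weight.
graph_distances <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / igraph::E(g)$weight
  igraph::distances(g, weights = len)
}

# Mean Onnela weighted clustering coefficient; weights normalized by max.
onnela_clustering <- function(w) {
  wh <- (w / max(w))^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(wh %*% wh %*% wh)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

#' FC within and between resting-state networks
#'
#' Entry (p, q) is the mean FC over region pairs with RSN labels p and q;
#' within-network entries (p == q) exclude self-pairs. Invariant to region
#' ordering.
#'
#' @param fc An `fc_matrix`.
#' @param parcellation A `parcellation` whose every region carries an RSN
#'   label; within-network entries need at least 2 member regions.
#' @return K x K named matrix over the RSN labels present.
#' @export
rsn_fc <- function(fc, parcellation = attr(fc, "parcellation")) {
  if (any(parcellation$rsn == "unassigned"))
    abort("every region needs an RSN label for network aggregation")
  labs <- intersect(RSN_LABELS, unique(parcellation$rsn))
  K <- length(labs)
  out <- matrix(NA_real_, K, K, dimnames = list(labs, labs))
  v <- unclass(fc)
  for (p in seq_len(K)) {
    ip <- which(parcellation$rsn == labs[p])
    for (q in p:K) {
      if (p == q) {
        if (length(ip) < 2)
          abort(sprintf("RSN %s has fewer than 2 members", labs[p]))
        block <- v[ip, ip]
        out[p, p] <- mean(block[upper.tri(block)])
      } else {
        iq <- which(parcellation$rsn == labs[q])
        out[p, q] <- out[q, p] <- mean(v[ip, iq])
      }
    }
  }
  out
}

#' Split regions by structural connection strength to a seed
#'
#' Ranks non-seed regions by their SC weight to the seed (ties broken by
#' region id, ascending) and returns the strongest `top_k` as the High-SC
#' group and the rest as Low-SC, plus every region's FC with the seed.
#'
#' @param fc An `fc_matrix`.
#' @param sc A `structural_connectome`.
#' @param seed_region 0-based seed region id.
#' @param top_k High-SC group size (default 10; must be < n - 1).
#' @return List with `high_sc`, `low_sc` (0-based id vectors) and
#'   `fc_to_seed` (named by region id, seed excluded).
#' @export
seed_fc_split <- function(fc, sc, seed_region, top_k = 10) {
  n <- nrow(sc)
  if (top_k >= n) abort("top_k must be smaller than the number of regions")
  s1 <- seed_region + 1L
  others <- setdiff(seq_len(n), s1)
  wts <- unclass(sc)[others, s1]
  if (all(wts == 0)) warn("all SC weights to the seed are zero; ranking is degenerate")
  ord <- others[order(-wts, others)]
  high <- sort(ord[seq_len(top_k)]) - 1L
  low <- sort(ord[-seq_len(top_k)]) - 1L
  fcv <- unclass(fc)[others, s1]
  names(fcv) <- others - 1L
  list(high_sc = high, low_sc = low, fc_to_seed = fcv)
}

#' Rank correlation between SC-to-seed and BOLD change
#'
#' Among candidate regions (stimulated regions excluded), retains those
#' whose SC weight to the seed is within the strongest `sc_sparsity`
#' fraction, then Spearman-correlates SC weight with the per-region
#' BOLD-change t-value.
#'
#' @param sc A `structural_connectome`.
#' @param t_values Length-n vector of per-region BOLD-change t-values
#'   (entries for excluded regions are ignored).
#' @param seed_region 0-based anodal seed id.
#' @param exclude Further 0-based region ids to drop (e.g. the cathodal
#'   region).
#' @param sc_sparsity Fraction of candidates retained by SC strength
#'   (default 0.2); at least 4 regions must survive.
#' @return List with `rho`, `p`, `n_retained`, `retained` (0-based ids).
#' @export
sc_bold_correlation <- function(sc, t_values, seed_region,
                                exclude = integer(0), sc_sparsity = 0.2) {
  n <- nrow(sc)
  if (length(t_values) != n) abort("t_values must have one entry per region")
  drop1 <- c(seed_region, exclude) + 1L
  cand <- setdiff(seq_len(n), drop1)
  wts <- unclass(sc)[cand, seed_region + 1L]
  k <- ceiling(sc_sparsity * length(cand))
  keep <- cand[order(-wts, cand)][seq_len(k)]
  if (length(keep) < 4)
    abort("fewer than 4 regions retained at this SC sparsity")
  res <- spearman_cor(unclass(sc)[keep, seed_region + 1L], t_values[keep])
  list(rho = res$rho, p = res$p, n_retained = length(keep),
       retained = sort(keep) - 1L)
}

#' @rdname network_analysis
#' @param x An `fc_matrix`.
#' @param ... Unused.
#' @method tidy fc_matrix
#' @export
tidy.fc_matrix <- function(x, ...) {
  parc <- attr(x, "parcellation")
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(from = parc$name[idx[, 1]], to = parc$name[idx[, 2]],
                 fc = unclass(x)[idx])
}
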