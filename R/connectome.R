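#' @title Parcellations and structural connectomes
#' @name connectome
#' @description
#' A parcellation is an ordered table of cortical regions (0-based `id`,
#' unique `name`, `hemisphere` L/R, and an optional resting-state-network
#' label). A structural connectome is the nonnegative symmetric coupling
#' matrix \eqn{C_{ij}} that gates inter-regional input in the mean-field
#' model; before simulation it is scaled so that its maximum element is 0.2.
#' Region order is the file's row order and is shared by every matrix and
#' vector in the package.
NULL

RSN_LABELS <- c("FPN", "DMN", "LIM", "DAN", "VAN", "SMN", "VIS")

new_parcellation <- function(df) {
  df <- tibble::as_tibble(df)
  structure(df, class = c("parcellation", class(df)))
}

validate_parcellation <- function(df) {
  req <- c("id", "name", "hemisphere")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    abort(paste0("parcellation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (!"rsn" %in% names(df)) df$rsn <- "unassigned"
  df$rsn[is.na(df$rsn) | df$rsn == ""] <- "unassigned"
  n <- nrow(df)
  if (n < 2) abort("a parcellation needs at least 2 regions")
  if (anyDuplicated(df$name)) abort("duplicate region names in parcellation")
  if (!identical(sort(as.integer(df$id)), 0:(n - 1)))
    abort("region ids must be 0..n-1 with no gaps")
  if (!all(df$hemisphere %in% c("L", "R")))
    abort("hemisphere must be 'L' or 'R'")
  bad <- setdiff(unique(df$rsn), c(RSN_LABELS, "unassigned"))
  if (length(bad) > 0)
    abort(paste0("unknown RSN label(s): ", paste(bad, collapse = ", ")))
  df <- df[order(df$id), c("id", "name", "hemisphere", "rsn")]
  df$id <- as.integer(df$id)
  new_parcellation(df)
}

#' Read a region parcellation table
#'
#' Reads a comma- or tab-delimited table with columns `id` (0-based region
#' index), `name`, `hemisphere` (`L`/`R`) and optionally `rsn` (one of the
#' seven canonical resting-state networks FPN, DMN, LIM, DAN, VAN, SMN, VIS,
#' or `unassigned`). Any atlas size n >= 2 is accepted; the 68-region
#' Desikan-Killiany and the 148-region Destrieux parcellations are the
#' typical cases.
#'
#' @param path Path to the delimited text file (delimiter auto-detected).
#' @return A `parcellation` tibble with columns `id`, `name`, `hemisphere`,
#'   `rsn`, ordered by `id`.
#' @export
read_parcellation <- function(path) {
  df <- readr::read_delim(path, delim = guess_delim(path),
                          show_col_types = FALSE, progress = FALSE)
  validate_parcellation(df)
}

#' Synthesize a parcellation
#'
#' Builds an n-region parcellation with alternating hemispheres and
#' resting-state-network labels assigned cyclically over the seven canonical
#' networks, for fully in-silico studies.
#'
#' @param n Number of regions (>= 2).
#' @return A `parcellation` tibble.
#' @export
synthetic_parcellation <- function(n = 68) {
  if (n < 2) abort("n must be >= 2")
  validate_parcellation(tibble::tibble(
    id = 0:(n - 1),
    name = sprintf("region_%03d", 0:(n - 1)),
    hemisphere = rep(c("L", "R"), length.out = n),
    rsn = rep(RSN_LABELS, length.out = n)
  ))
}

guess_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

n_regions <- function(parcellation) nrow(parcellation)

new_connectome <- function(weights, parcellation, scaled) {
  dimnames(weights) <- NULL
  structure(weights, parcellation = parcellation, scaled = scaled,
            class = c("structural_connectome", "matrix", "array"))
}

#' @export
print.structural_connectome <- function(x, ...) {
  cat(sprintf("<structural_connectome> %d x %d, max %.4g, %s\n",
              nrow(x), ncol(x), max(x),
              if (isTRUE(attr(x, "scaled"))) "scaled" else "unscaled"))
  invisible(x)
}

#' Read a structural-connectivity matrix
#'
#' Reads a square delimited text matrix (no header) of nonnegative coupling
#' weights, one row per region in parcellation order. Tiny numerical
#' asymmetry (relative Frobenius asymmetry below `tol`) is repaired by
#' averaging with the transpose; larger asymmetry is an error, since
#' tractography-derived matrices are nominally symmetric and silent large
#' repairs hide upstream bugs. The diagonal is zeroed.
#'
#' @param path Path to the matrix file.
#' @param parcellation A `parcellation`; the matrix dimension must match.
#' @param tol Relative Frobenius asymmetry tolerance (default 1e-8).
#' @return An unscaled `structural_connectome`.
#' @export
read_sc <- function(path, parcellation, tol = 1e-8) {
  # scan() parses doubles with correctly-rounded strtod, so text written at
  # full precision round-trips bit-exactly
  rows <- lapply(readLines(path), function(l)
    scan(text = l, what = double(), quiet = TRUE,
         sep = guess_delim_matrix(path)))
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) abort("SC matrix rows have unequal lengths")
  m <- do.call(rbind, rows)
  as_connectome(m, parcellation, tol = tol)
}

guess_delim_matrix <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else " "
}

as_connectome <- function(m, parcellation, tol = 1e-8) {
  n <- n_regions(parcellation)
  if (nrow(m) != ncol(m)) abort("SC matrix must be square")
  if (nrow(m) != n)
    abort(sprintf("SC dimension %d does not match parcellation (%d regions)",
                  nrow(m), n))
  if (any(!is.finite(m))) abort("SC matrix contains non-finite entries")
  if (any(m < 0)) abort("SC matrix contains negative entries")
  nf <- norm(m, "F")
  asym <- if (nf > 0) norm(m - t(m), "F") / nf else 0
  if (asym > tol)
    abort(sprintf("SC matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new_connectome(m, parcellation, scaled = FALSE)
}

#' Write a structural-connectivity matrix
#'
#' Full-precision tab-delimited export; `read_sc()` round-trips every entry
#' exactly.
#'
#' @param sc A `structural_connectome`.
#' @param path Output path.
#' @export
write_sc <- function(sc, path) {
  lines <- apply(unclass(sc), 1L,
                 function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Group-consensus structural connectome
#'
#' An edge is retained iff its weight is strictly nonzero in at least
#' `presence_fraction` of the subjects; retained edges carry the arithmetic
#' mean weight across all subjects (zeros included), other edges are 0. This
#' suppresses false-positive connections arising from subject-specific
#' tractography noise.
#'
#' @param subject_matrices List of `structural_connectome` objects of equal
#'   dimension.
#' @param presence_fraction Fraction of subjects in (0, 1] in which an edge
#'   must be present (default 0.5).
#' @return An unscaled consensus `structural_connectome`.
#' @export
consensus_sc <- function(subject_matrices, presence_fraction = 0.5) {
  if (length(subject_matrices) < 1) abort("need at least one subject matrix")
  if (presence_fraction <= 0 || presence_fraction > 1)
    abort("presence_fraction must be in (0, 1]")
  dims <- vapply(subject_matrices, nrow, integer(1))
  if (length(unique(dims)) != 1)
    abort("subject matrices have mismatched dimensions")
  arr <- simplify2array(lapply(subject_matrices, unclass))
  presence <- apply(arr != 0, c(1, 2), mean)
  avg <- apply(arr, c(1, 2), mean)
  avg[presence < presence_fraction] <- 0
  new_connectome(avg, attr(subject_matrices[[1]], "parcellation"),
                 scaled = FALSE)
}

#' Scale a connectome to a fixed maximum element
#'
#' Multiplies every entry by `target_max / max(C)` so the maximum element is
#' exactly `target_max` (0.2 by default), the normalization under which the
#' mean-field model's coupling parameters are calibrated. Idempotent.
#'
#' @param sc A `structural_connectome` with at least one positive entry.
#' @param target_max Target maximum element (default 0.2).
#' @return A scaled `structural_connectome`.
#' @export
scale_sc <- function(sc, target_max = 0.2) {
  mx <- max(sc)
  if (mx <= 0) abort("cannot scale an all-zero SC matrix")
  w <- unclass(sc) / mx * target_max
  new_connectome(w, attr(sc, "parcellation"), scaled = TRUE)
}

#' Synthesize a structural connectome
#'
#' Draws an Erdos-Renyi edge mask at the requested density with log-normal
#' weights (meanlog 0, sdlog 1 before scaling), reproducing the sparse,
#' heavy-tailed character of tract-count matrices. Graph connectivity is
#' enforced by redrawing (bounded); the result is symmetric, zero-diagonal,
#' and already scaled to maximum element 0.2. Deterministic given `seed`.
#'
#' @param n Number of regions (>= 2).
#' @param density Target edge density in (0, 1].
#' @param seed Integer seed.
#' @param parcellation Optional `parcellation` (defaults to
#'   `synthetic_parcellation(n)`).
#' @param max_redraws Redraw budget for the connectivity requirement.
#' @return A scaled `structural_connectome`.
#' @export
synthetic_sc <- function(n, density = 0.3, seed = 1, parcellation = NULL,
                         max_redraws = 100L) {
  if (n < 2) abort("n must be >= 2")
  if (density <= 0 || density > 1) abort("density must be in (0, 1]")
  if (is.null(parcellation)) parcellation <- synthetic_parcellation(n)
  w <- with_seed(seed, {
    for (attempt in seq_len(max_redraws)) {
      m <- matrix(0, n, n)
      ut <- upper.tri(m)
      n_edges <- sum(ut)
      mask <- runif(n_edges) < density
      if (n == 2) mask <- TRUE
      wts <- rlnorm(n_edges, meanlog = 0, sdlog = 1) * mask
      m[ut] <- wts
      m <- m + t(m)
      g <- igraph::graph_from_adjacency_matrix(m > 0, mode = "undirected")
      if (igraph::is_connected(g)) break
      m <- NULL
    }
    if (is.null(m))
      abort(sprintf("density %.3g too low to connect %d regions after %d draws",
                    density, n, max_redraws))
    m
  })
  scale_sc(new_connectome(w, parcellation, scaled = FALSE))
}

#' @rdname connectome
#' @param x A `structural_connectome`.
#' @param ... Unused.
#' @method tidy structural_connectome
#' @export
tidy.structural_connectome <- function(x, ...) {
  parc <- attr(x, "parcellation")
  n <- nrow(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    from = parc$name[idx[, 1]],
    to = parc$name[idx[, 2]],
    weight = unclass(x)[idx]
  )
}
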