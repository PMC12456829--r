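#' @title In-silico stimulation studies
#' @name experiment
#' @description
#' A study runs every condition (always including the unstimulated
#' `"Without"` baseline) for a fixed number of seeded runs, pushes each run
#' through the full pipeline (mean-field simulation, hemodynamics,
#' post-processing, static FC, graph metrics, RSN aggregation, complexity,
#' dynamic FC, synchrony), and then contrasts each stimulation condition
#' against the baseline with paired edgewise statistics, the SC-to-BOLD
#' rank correlation, and phase-resolved dFC summaries. Run r of every
#' condition shares the same noise seed offset, which is what makes the
#' paired tests meaningful in silico. Every number in the outputs is
#' reconstructible from the manifest (configuration plus seeds).
NULL

#' Study configuration
#'
#' @param parcellation A `parcellation`.
#' @param sc A scaled `structural_connectome`.
#' @param efields Named list of `efield_samples`, one per stimulation
#'   condition label (no entry for `"Without"`).
#' @param conditions Condition labels; must include `"Without"`.
#' @param runs_per_condition Runs per condition (>= 2; default 30).
#' @param onset_s,duration_s Stimulus timing on the retained timeline
#'   (defaults 0 and 60 s: the stimulus starts at the first retained TR).
#' @param discard_s Initial transient discarded from the BOLD (default 60).
#' @param tr_s Repetition time (default 0.72).
#' @param n_trs Retained TR count (default 1200).
#' @param lambda_coeff,k_gain Field-to-gating coupling (defaults 0.13, 1).
#' @param mfm,hemo Parameter blocks (defaults [mfm_params()],
#'   [hemo_params()]).
#' @param dt_s,record_every Integration step and recording stride.
#' @param window_len_tr dFC window length (default 40).
#' @param static_trs Static-analysis slice length (default 130).
#' @param sc_sparsity SC sparsity threshold for the seed rank-correlation
#'   (default 0.2; small parcellations need a higher fraction to retain
#'   enough regions — the smoke study uses 0.3, within the validated
#'   0.2-0.5 range).
#' @param base_seed Base seed; run r of condition c uses
#'   `base_seed + 1000 c + r`.
#' @param out_dir Optional output directory; `NULL` keeps results in
#'   memory only.
#' @return A `study_config` list.
#' @export
study_config <- function(parcellation, sc, efields, conditions,
                         runs_per_condition = 30, onset_s = 0,
                         duration_s = 60, discard_s = 60, tr_s = 0.72,
                         n_trs = 1200, lambda_coeff = 0.13, k_gain = 1,
                         mfm = mfm_params(), hemo = hemo_params(),
                         dt_s = 1e-4, record_every = 10L,
                         window_len_tr = 40, static_trs = 130,
                         sc_sparsity = 0.2, base_seed = 1, out_dir = NULL) {
  if (!"Without" %in% conditions)
    abort("conditions must include the 'Without' baseline")
  if (runs_per_condition < 2) abort("need at least 2 runs per condition")
  active <- setdiff(conditions, "Without")
  missing_ef <- setdiff(active, names(efields))
  if (length(missing_ef) > 0)
    abort(paste0("no e-field supplied for condition(s): ",
                 paste(missing_ef, collapse = ", ")))
  structure(list(parcellation = parcellation, sc = sc, efields = efields,
                 conditions = conditions,
                 runs_per_condition = as.integer(runs_per_condition),
                 onset_s = onset_s, duration_s = duration_s,
                 discard_s = discard_s, tr_s = tr_s, n_trs = as.integer(n_trs),
                 lambda_coeff = lambda_coeff, k_gain = k_gain,
                 mfm = mfm, hemo = hemo, dt_s = dt_s,
                 record_every = as.integer(record_every),
                 window_len_tr = as.integer(window_len_tr),
                 static_trs = as.integer(static_trs),
                 sc_sparsity = sc_sparsity,
                 base_seed = as.integer(base_seed), out_dir = out_dir),
            class = "study_config")
}

run_seed <- function(config, cond_index, run) {
  config$base_seed + 1000L * cond_index + run
}

build_condition_protocol <- function(config, label) {
  if (label == "Without")
    without_protocol(config$parcellation, config$onset_s, config$duration_s)
  else
    build_protocol(config$efields[[label]],
                   crucial_regions(config$efields[[label]]),
                   lambda_coeff = config$lambda_coeff,
                   k_gain = config$k_gain, onset_s = config$onset_s,
                   duration_s = config$duration_s, label = label)
}

# Single condition x run pipeline pass: simulate, BOLD, per-run analyses.
run_one <- function(config, protocol, seed) {
  sim_total <- config$discard_s + config$n_trs * config$tr_s
  sim_proto <- protocol
  sim_proto$onset_s <- protocol$onset_s + config$discard_s
  traj <- simulate_mfm(config$mfm, config$sc, sim_proto,
                       sim_config(total_s = sim_total, dt_s = config$dt_s,
                                  seed = seed,
                                  record_every = config$record_every))
  stim_lo <- sim_proto$onset_s
  stim_hi <- sim_proto$onset_s + sim_proto$duration_s
  in_stim <- traj$time_s >= stim_lo & traj$time_s < stim_hi
  rate_during <- rowMeans(traj$H[, in_stim, drop = FALSE])
  gating_during <- rowMeans(traj$S[, in_stim, drop = FALSE])
  clamp_hits <- traj$clamp_hits

  bold <- balloon_windkessel(traj, config$hemo)
  rm(traj)
  bold <- postprocess_bold(bold, discard_s = config$discard_s,
                           tr_s = config$tr_s, n_points = config$n_trs)
  bold$protocol <- protocol
  bold <- segment_periods(bold, protocol, static_trs = config$static_trs)

  fc_static <- bold_fc(bold, bold$static_slice)
  gm <- graph_metrics(fc_static)
  rsn <- rsn_fc(fc_static, config$parcellation)
  dfc <- phase_partition(sliding_dfc(bold, config$window_len_tr), bold)
  dfc_summary <- tidy(dfc)
  sync <- kuramoto(bold, by_period = TRUE)
  comp <- complexity_report(bold)
  period_bold <- purrr::map_dfr(names(bold$period_marks), function(nm) {
    tibble::tibble(period = nm, region_id = config$parcellation$id,
                   mean_bold = rowMeans(
                     bold$data[, bold$period_marks[[nm]], drop = FALSE]))
  })

  list(bold = bold, fc_static = fc_static, graph = gm, rsn = rsn,
       dfc_summary = dfc_summary, sync = sync$per_period,
       complexity = comp, period_bold = period_bold,
       rate_during = rate_during, gating_during = gating_during,
       clamp_hits = clamp_hits, seed = seed)
}

#' Run a full in-silico study
#'
#' Executes every condition x run, aggregates per-run analyses into tidy
#' tables, computes all condition-vs-Without contrasts with FDR control,
#' the SC-to-BOLD-change Spearman correlation around the anodal seed, and
#' phase-resolved dFC summaries. With `out_dir` set, BOLD matrices, metric
#' tables, contrast tables and a manifest (config hash + per-run seeds) are
#' written as delimited text; rerunning the same configuration reproduces
#' the files bit-identically.
#'
#' @param config A `study_config`.
#' @param keep_bold Keep per-run `bold_series` objects in the returned
#'   bundle (default FALSE to bound memory).
#' @return A `study_bundle` list; see Details.
#' @details The bundle contains `runs` (tibble of condition/run/seed/clamp
#'   hits), `graph` / `sync` / `complexity` / `dfc` / `period_bold` tidy
#'   tables, `fc` (per-condition n x n x R arrays), `rate_during` and
#'   `gating_during` (per-condition region x R matrices), `contrasts`
#'   (per active condition: edgewise `condition_contrast`, per-region BOLD
#'   t-values, `sc_bold` rank correlation, crucial-region ids), and
#'   `config`.
#' @export
run_study <- function(config, keep_bold = FALSE) {
  protocols <- lapply(stats::setNames(config$conditions, config$conditions),
                      function(lb) build_condition_protocol(config, lb))
  n <- n_regions(config$parcellation)
  R <- config$runs_per_condition
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  per_run <- list()
  fc_arrays <- list()
  rate_mats <- list()
  gating_mats <- list()
  bundle_tabs <- list(graph = list(), sync = list(), complexity = list(),
                      dfc = list(), period_bold = list(), runs = list())
  bold_store <- list()

  for (ci in seq_along(config$conditions)) {
    lb <- config$conditions[ci]
    fc_arr <- array(NA_real_, c(n, n, R))
    rate_m <- matrix(NA_real_, n, R)
    gating_m <- matrix(NA_real_, n, R)
    for (r in seq_len(R)) {
      seed <- run_seed(config, ci, r)
      res <- run_one(config, protocols[[lb]], seed)
      fc_arr[, , r] <- unclass(res$fc_static)
      rate_m[, r] <- res$rate_during
      gating_m[, r] <- res$gating_during
      bundle_tabs$graph[[length(bundle_tabs$graph) + 1]] <-
        dplyr::mutate(res$graph, condition = lb, run = r, .before = 1)
      bundle_tabs$sync[[length(bundle_tabs$sync) + 1]] <-
        dplyr::mutate(res$sync, condition = lb, run = r, .before = 1)
      bundle_tabs$complexity[[length(bundle_tabs$complexity) + 1]] <-
        dplyr::mutate(res$complexity, condition = lb, run = r, .before = 1)
      bundle_tabs$dfc[[length(bundle_tabs$dfc) + 1]] <-
        dplyr::mutate(res$dfc_summary, condition = lb, run = r, .before = 1)
      bundle_tabs$period_bold[[length(bundle_tabs$period_bold) + 1]] <-
        dplyr::mutate(res$period_bold, condition = lb, run = r, .before = 1)
      bundle_tabs$runs[[length(bundle_tabs$runs) + 1]] <-
        tibble::tibble(condition = lb, run = r, seed = seed,
                       clamp_hits = res$clamp_hits)
      if (!is.null(out_dir)) {
        rd <- file.path(out_dir, lb, sprintf("run_%02d", r))
        dir.create(rd, recursive = TRUE, showWarnings = FALSE)
        write_bold(res$bold, file.path(rd, "bold.tsv"))
      }
      if (keep_bold) bold_store[[paste(lb, r, sep = "_")]] <- res$bold
    }
    fc_arrays[[lb]] <- fc_arr
    rate_mats[[lb]] <- rate_m
    gating_mats[[lb]] <- gating_m
  }

  tabs <- lapply(bundle_tabs, dplyr::bind_rows)
  contrasts <- list()
  for (lb in setdiff(config$conditions, "Without")) {
    crucial <- which(protocols[[lb]]$theta != 0) - 1L
    anodal <- crucial[which.max(protocols[[lb]]$theta[crucial + 1L])]
    cathodal <- crucial[which.min(protocols[[lb]]$theta[crucial + 1L])]
    edge <- edgewise_contrast(fc_arrays[[lb]], fc_arrays[["Without"]])
    tvals <- region_bold_t(tabs$period_bold, lb)
    scb <- sc_bold_correlation(config$sc, tvals, seed_region = anodal,
                               exclude = setdiff(crucial, anodal),
                               sc_sparsity = config$sc_sparsity)
    contrasts[[lb]] <- list(edgewise = edge, bold_t = tvals,
                            sc_bold = scb, crucial = crucial,
                            anodal = anodal, cathodal = cathodal)
  }

  bundle <- structure(c(tabs, list(fc = fc_arrays, rate_during = rate_mats,
                                   gating_during = gating_mats,
                                   contrasts = contrasts,
                                   protocols = protocols,
                                   bold = if (keep_bold) bold_store,
                                   config = config)),
                      class = "study_bundle")
  if (!is.null(out_dir)) write_bundle_tables(bundle, out_dir)
  bundle
}

# Per-region paired t of mean During BOLD (condition) vs the matched window
# of the Without runs.
region_bold_t <- function(period_bold, label) {
  a <- dplyr::filter(period_bold, .data$condition == label,
                     .data$period == "During")
  b <- dplyr::filter(period_bold, .data$condition == "Without",
                     .data$period == "Without")
  ids <- sort(unique(a$region_id))
  vapply(ids, function(id) {
    av <- a$mean_bold[a$region_id == id][order(a$run[a$region_id == id])]
    bv <- b$mean_bold[b$region_id == id][order(b$run[b$region_id == id])]
    paired_t(av, bv)$t
  }, numeric(1))
}

write_bundle_tables <- function(bundle, out_dir) {
  readr::write_csv(bundle$runs, file.path(out_dir, "runs.csv"))
  readr::write_csv(bundle$graph, file.path(out_dir, "graph_metrics.csv"))
  readr::write_csv(bundle$sync, file.path(out_dir, "synchrony.csv"))
  readr::write_csv(bundle$complexity, file.path(out_dir, "complexity.csv"))
  readr::write_csv(bundle$dfc, file.path(out_dir, "dfc_window_means.csv"))
  cdir <- file.path(out_dir, "contrasts")
  dir.create(cdir, showWarnings = FALSE)
  for (lb in names(bundle$contrasts)) {
    readr::write_csv(tidy(bundle$contrasts[[lb]]$edgewise),
                     file.path(cdir, paste0(lb, "_edgewise.csv")))
  }
  cfg <- bundle$config
  manifest <- list(
    conditions = cfg$conditions, runs_per_condition = cfg$runs_per_condition,
    n_regions = n_regions(cfg$parcellation), onset_s = cfg$onset_s,
    duration_s = cfg$duration_s, discard_s = cfg$discard_s, tr_s = cfg$tr_s,
    n_trs = cfg$n_trs, lambda = cfg$lambda_coeff, k = cfg$k_gain,
    dt_s = cfg$dt_s, base_seed = cfg$base_seed,
    window_len_tr = cfg$window_len_tr, static_trs = cfg$static_trs,
    mfm = unclass(cfg$mfm), hemo = unclass(cfg$hemo),
    seeds = stats::setNames(as.list(bundle$runs$seed),
                            paste(bundle$runs$condition, bundle$runs$run,
                                  sep = "_")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d conditions x %d runs, %d regions\n",
              length(x$config$conditions), x$config$runs_per_condition,
              n_regions(x$config$parcellation)))
  invisible(x)
}

#' Reduced smoke-scale study
#'
#' A complete study at desk scale: 16 synthetic regions, 5 runs per
#' condition, 300 retained TRs, one bipolar stimulation condition against
#' the `"Without"` baseline. Exercises every analysis stage in minutes.
#'
#' @param base_seed Base seed (default 1).
#' @param runs_per_condition Runs (default 5).
#' @param n Regions (default 16).
#' @param n_trs Retained TRs (default 300).
#' @param out_dir Optional output directory.
#' @param ... Further overrides passed to [study_config()].
#' @return A `study_bundle`.
#' @export
smoke_study <- function(base_seed = 1, runs_per_condition = 5, n = 16,
                        n_trs = 300, out_dir = NULL, ...) {
  parc <- synthetic_parcellation(n)
  sc <- synthetic_sc(n, density = 0.3, seed = base_seed, parcellation = parc)
  ef <- synthetic_efield(parc, anodal_region = 4L,
                         cathodal_region = 12L %% n, seed = base_seed + 1)
  cfg <- study_config(parc, sc, efields = list("F3a-Fp2c" = ef),
                      conditions = c("Without", "F3a-Fp2c"),
                      runs_per_condition = runs_per_condition,
                      n_trs = n_trs, base_seed = base_seed,
                      sc_sparsity = 0.3, out_dir = out_dir, ...)
  run_study(cfg)
}
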