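# End-to-end orchestration: synthetic scenario -> shifts -> SSP ->
# reweighting -> HDX, with file outputs. The thin command-line wrapper in
# inst/cli/polyq-ens.R calls these functions.

#' Merge observationally indistinguishable conformers
#'
#' Conformers with identical secondary-structure strings have identical
#' predicted-shift rows under the linear forward model, so their weights
#' are not individually identifiable; this merges each such group into
#' its first representative, summing any supplied weights.
#'
#' @param pool list of `conformer` objects.
#' @param w optional weights to aggregate alongside.
#' @return List with `pool`, `weights` (or NULL), and `group` (index of
#'   the representative each original conformer maps to).
#' @export
collapse_duplicate_conformers <- function(pool, w = NULL) {
  ss <- vapply(pool, function(cf) unclass(conformer_ss(cf)), character(1))
  rep_idx <- match(ss, unique(ss))
  keep <- !duplicated(ss)
  out_w <- NULL
  if (!is.null(w)) out_w <- as.numeric(tapply(w, rep_idx, sum))
  list(pool = pool[keep], weights = out_w, group = rep_idx)
}

#' Run the synthetic ensemble-analysis pipeline for one scenario
#'
#' Samples a conformer pool, synthesises ensemble-averaged experimental
#' shifts under ground-truth weights, refits weights by simplex-
#' constrained least squares and summarises per-residue secondary-
#' structure probabilities.
#'
#' @param scenario a [make_scenario()].
#' @param K pool size (default `scenario$pool_size`).
#' @param nuclei nuclei entering the fit.
#' @param truth `"uniform"` for equal generating weights or `"sparse"`
#'   for a sparse Dirichlet mixture; or a numeric simplex vector.
#' @param l2 ridge penalty of the fit.
#' @param build_coords build coordinates for the pool.
#' @return List: `scenario`, `pool`, `truth_weights`, `exp` (synthetic
#'   shift table), `M` (prediction matrix), `w` (fitted weights),
#'   `summary` (ensemble summary with diagnostics).
#' @export
run_scenario_pipeline <- function(scenario, K = scenario$pool_size,
                                  nuclei = c("H", "N", "HA", "CA", "CB"),
                                  truth = "uniform", l2 = 0,
                                  build_coords = FALSE) {
  pool <- sample_pool(scenario, K = K, build_coords = build_coords)
  w0 <- if (is.numeric(truth)) {
    truth
  } else if (identical(truth, "sparse")) {
    sparse_truth_weights(length(pool),
                         seed = scenario_seed(scenario, "truth"))
  } else {
    rep(1 / length(pool), length(pool))
  }
  exp_tbl <- synth_experimental_shifts(
    pool, w0, noise_sd = scenario$noise_sd,
    seed = scenario_seed(scenario, "shifts"), nuclei = nuclei)
  M <- attr(exp_tbl, "matrix")
  w <- fit_weights(M, exp_tbl, l2 = l2)
  summ <- ensemble_summary(pool, as.numeric(w), M = M, exp = exp_tbl)
  list(scenario = scenario, pool = pool, truth_weights = w0,
       exp = exp_tbl, M = M, w = w, summary = summ)
}

#' Run the full demonstration pipeline
#'
#' Generates the normal-length and one expanded scenario, runs secondary
#' shift + SSP analysis on the synthetic shifts, fits both ensembles,
#' classifies synthetic HDX series, and writes `ssp.csv`,
#' `ensemble.json`, `hdx_map.csv` and `config.json` into `outdir`.
#' Deterministic for a given seed.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed.
#' @param K pool size per scenario.
#' @param window SSP window length.
#' @param ssp_threshold segment-calling threshold.
#' @return Invisibly, a list of the main results.
#' @export
run_pipeline <- function(outdir, seed = 1L, K = 60L, window = 5L,
                         ssp_threshold = 0.3) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rc <- random_coil_table()

  sc10 <- make_scenario("normal_10Q", seed = seed, pool_size = K)
  sc22 <- make_scenario("expanded_22Q", seed = seed, pool_size = K)
  r10 <- run_scenario_pipeline(sc10)
  r22 <- run_scenario_pipeline(sc22)

  prof <- secondary_shifts(r10$exp, rc)
  ssp <- ssp_score(prof, window = window)
  ssp_out <- merge(as.data.frame(prof)[c("index", "aa", "dCA", "dCB",
                                         "dCaCb")],
                   as.data.frame(ssp)[c("index", "ssp")], by = "index")
  utils::write.csv(ssp_out, file.path(outdir, "ssp.csv"),
                   row.names = FALSE, quote = FALSE)

  cmp <- compare_variants(r10$summary, r22$summary,
                          region_a = sc10$polyq_range,
                          region_b = sc22$polyq_range)
  ens <- list(
    normal_10Q = list(weights = r10$summary$weights,
                      effective_size = r10$summary$effective_size,
                      profile = r10$summary$profile,
                      diagnostics = r10$summary$diagnostics),
    expanded_22Q = list(weights = r22$summary$weights,
                        effective_size = r22$summary$effective_size,
                        profile = r22$summary$profile,
                        diagnostics = r22$summary$diagnostics),
    polyq_region_mean_delta_p_H = cmp$region_mean_delta,
    solver = attr(r10$w, "solver"))
  jsonlite::write_json(ens, file.path(outdir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  hdx10 <- classify_hdx(synth_hdx(sc10))
  write_hdx_map_csv(hdx10, file.path(outdir, "hdx_map.csv"))

  cfg <- list(seed = seed, K = K, window = window,
              ssp_threshold = ssp_threshold,
              noise_sd = sc10$noise_sd,
              version = as.character(utils::packageVersion("polyqens")))
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE)
  invisible(list(r10 = r10, r22 = r22, ssp = ssp, hdx = hdx10,
                 compare = cmp))
}
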