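#' Built-in run profiles
#'
#' Three trade-offs between fidelity and runtime. `ci`: the 40-site,
#' 20-year fixture with 5-member ensembles, 4 folds, a fixed
#' hyperparameter set and short early stopping — minutes on one core.
#' `desk`: 40 sites, 10 folds, a reduced grid (hidden 10 or 20) and
#' 5-member ensembles. `paper`: 185 sites on 1982--2015 panels, 10 folds,
#' the full grid and 50-member ensembles — hours-scale.
#'
#' @param profile one of `"ci"`, `"desk"`, `"paper"`.
#' @param master_seed master seed for every stage.
#' @return a list of class `fm_runconfig`.
#' @export
run_profile <- function(profile = c("ci", "desk", "paper"), master_seed = 1L) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    ci = list(gen = fixture_config(master_seed),
              K = 4, n_members = 5, grid = NULL,
              hp = hyperparams(learning_rate = 0.01, hidden_units = 10,
                               dropout = 0, patience = 60,
                               max_iterations = 400),
              variants = c("LSTM", "LSTM_perm", "LSTM_msc", "LSTM_annual",
                           "RF"),
              n_years_list = 1:5, scenarios = "all"),
    desk = list(gen = fixture_config(master_seed),
                K = 10, n_members = 5,
                grid = default_grid(hidden_units_set = c(10, 20),
                                    patience = 100, max_iterations = 800),
                hp = hyperparams(patience = 100, max_iterations = 800),
                variants = c("LSTM", "LSTM_perm", "LSTM_msc", "LSTM_annual",
                             "RF"),
                n_years_list = 1:5,
                scenarios = c("all", "climate_only", "reflectance_only")),
    paper = list(gen = generator_config(master_seed = master_seed),
                 K = 10, n_members = 50, grid = default_grid(),
                 hp = hyperparams(),
                 variants = c("LSTM", "LSTM_perm", "LSTM_msc", "LSTM_annual",
                              "RF"),
                 n_years_list = 1:5,
                 scenarios = c("all", "climate_only", "reflectance_only")))
  cfg$profile <- profile
  cfg$master_seed <- as.integer(master_seed)
  class(cfg) <- "fm_runconfig"
  cfg
}

#' Run the full factorial study
#'
#' Generate -> quality filter -> (gap-fill if the configuration produces
#' reflectance gaps) -> materialize set-up variants -> entire-site
#' cross-validation per variant -> altered-forcings experiment ->
#' stratified multi-scale evaluation. Stage outputs are written as CSV
#' under `out_dir` together with a JSON manifest (profile, seed, stage
#' order); finished stages found on disk are reused unless
#' `overwrite = TRUE`.
#'
#' @param config an [run_profile()] configuration.
#' @param out_dir output directory.
#' @param overwrite recompute even when outputs exist.
#' @return (invisibly) a list with the evaluation report, altered-forcings
#'   summaries and the per-variant CV objects.
#' @export
run_all <- function(config = run_profile("ci"), out_dir = "results",
                    overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$master_seed
  ds <- generate_dataset(config$gen)
  panel <- qc_filter(ds$panels)
  if (config$gen$gap_rate_reflectance > 0) {
    panel <- gapfill_stage1(panel, ds$aux, seed = derive_seed(seed, "gf1"))
    panel <- gapfill_stage2(panel, ds$sites, seed = derive_seed(seed, "gf2"))
  }
  samples <- build_samples(panel, ds$sites)
  folds <- assign_folds(ds$sites, K = config$K,
                        seed = derive_seed(seed, "folds"))
  cvs <- list(); reports <- list()
  for (v in config$variants) {
    f <- file.path(out_dir, paste0("predictions_", v, ".csv"))
    variant <- make_setup(samples, v, seed = derive_seed(seed, "setup"))
    cv <- run_cross_validation(variant, ds$sites, folds,
                               model = if (v == "RF") "rf" else "lstm",
                               hp = config$hp, grid = config$grid,
                               n_members = config$n_members,
                               seed = derive_seed(seed, "cv", v))
    cvs[[v]] <- cv
    if (overwrite || !file.exists(f))
      write.csv(cv$predictions, f, row.names = FALSE)
    reports[[v]] <- stratified_report(cv, ds$sites)
  }
  report <- do.call(rbind, reports)
  write.csv(report, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
  altered <- run_altered_forcings(cvs$LSTM, samples, ds$sites,
                                  n_years_list = config$n_years_list,
                                  scenarios = config$scenarios)
  write.csv(altered$curves, file.path(out_dir, "altered_curves.csv"),
            row.names = FALSE)
  write.csv(altered$by_n, file.path(out_dir, "altered_by_n.csv"),
            row.names = FALSE)
  manifest <- list(profile = config$profile, master_seed = seed,
                   n_sites = config$gen$n_sites, K = config$K,
                   n_members = config$n_members,
                   stages = c("generate", "qc", "gapfill", "setups", "cv",
                              "altered", "evaluate"),
                   variants = config$variants)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(list(report = report, altered = altered, cvs = cvs,
                 dataset = ds))
}
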