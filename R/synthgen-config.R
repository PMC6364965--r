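#' Configuration for the synthetic flux-site generator
#'
#' Bundles every knob of the generator into one validated list. The defaults
#' emulate the structure of a global forest eddy-covariance compilation:
#' 185 sites with monthly records 1982--2015, NEE observed only inside each
#' site's 3--12 year measurement window (placed in 2000--2015), cloud-driven
#' reflectance gaps that are worse in the tropics, occasional
#' disturbance/recovery trajectories, and an NEE whose respiration component
#' depends on past productivity through a single first-order carbon pool.
#'
#' @param n_sites number of sites to generate.
#' @param period integer `c(start_year, end_year)` of the monthly panel;
#'   must span at least 5 years.
#' @param lambda carbon-pool decay rate per month, in (0, 1]. The pool
#'   half-life is `log(2) / -log(1 - lambda)` months; `lambda = 1` with
#'   `gamma = 0` gives a memoryless NEE. `lambda = 0` (an infinite-memory
#'   pool) is rejected unless `allow_infinite_memory = TRUE`.
#' @param gamma fraction of last month's GPP entering the pool.
#' @param epsilon light-use efficiency: GPP per unit radiation x greenness
#'   (gC m-2 d-1 per W m-2).
#' @param resp_base,resp_temp_sens base respiration rate (month-1) and
#'   exponential temperature sensitivity (degC-1) of the pool turnover;
#'   `resp_temp_sens = 0.07` corresponds to Q10 of about 2.
#' @param c0 initial carbon pool (gC m-2 d-1 units of stored GPP).
#' @param disturbance_prob per-site probability of one disturbance event.
#' @param disturbance_drop fraction of greenness removed at the event.
#' @param recovery_tau exponential recovery time constant, months.
#' @param gap_rate_reflectance per-band per-month probability that a
#'   reflectance observation is lost to clouds.
#' @param tropical_gap_factor multiplier on the gap rate for tropical sites.
#' @param qc_alpha,qc_beta Beta distribution parameters of the monthly NEE
#'   quality fraction.
#' @param noise named list of noise scales: `tair`, `rg` (AR(1) stationary
#'   sd), `vpd`, `greenness` (month-scale AR(1) sd), `greenness_iav`
#'   (year-scale greenness anomaly sd, emulating drought years and good
#'   years; constant within a calendar year), `reflectance`, `tir`, `nee`
#'   (Gaussian sd), `precip_sdlog` (lognormal sd on the log scale; keeps
#'   precipitation positive), `aux` (auxiliary-band sd).
#' @param window_years integer `c(min, max)` length of the NEE measurement
#'   window in years.
#' @param window_period calendar years within which measurement windows are
#'   placed.
#' @param aux_start_year first year covered by the auxiliary reflectance
#'   table (the stand-in for a coarser-resolution satellite record used by
#'   stage-1 gap-filling).
#' @param pft_weights,hemisphere_north_prob sampling weights for plant
#'   functional types and the probability a site sits in the northern
#'   hemisphere.
#' @param climate_weights sampling weights of the four climate classes;
#'   a site's class is recovered deterministically from its |latitude| band
#'   (tropical < 23.5, arid < 35, temperate < 55, boreal otherwise).
#' @param allow_infinite_memory permit `lambda = 0`.
#' @param master_seed integer master seed; every random stream is derived
#'   from it hierarchically (master -> site -> variable).
#' @return a list of class `fm_config`.
#' @export
generator_config <- function(n_sites = 185L,
                             period = c(1982L, 2015L),
                             lambda = 0.2,
                             gamma = 1,
                             epsilon = 0.045,
                             resp_base = 0.085,
                             resp_temp_sens = 0.07,
                             c0 = 0,
                             disturbance_prob = 0.25,
                             disturbance_drop = 0.5,
                             recovery_tau = 36,
                             gap_rate_reflectance = 0.3,
                             tropical_gap_factor = 2.5,
                             qc_alpha = 18,
                             qc_beta = 1,
                             noise = list(),
                             window_years = c(3L, 12L),
                             window_period = c(2000L, 2015L),
                             aux_start_year = 2000L,
                             pft_weights = c(deciduous = 0.30, evergreen = 0.45,
                                             mixed = 0.15, savanna = 0.10),
                             climate_weights = c(arid = 0.10, boreal = 0.30,
                                                 temperate = 0.45, tropical = 0.15),
                             hemisphere_north_prob = 0.85,
                             allow_infinite_memory = FALSE,
                             master_seed = 1L) {
  noise_def <- list(tair = 1.5, rg = 15, vpd = 2, precip_sdlog = 0.4,
                    greenness = 0.03, greenness_iav = 0.06,
                    reflectance = 0.008, tir = 1, nee = 0.3, aux = 0.005)
  noise <- utils::modifyList(noise_def, noise)

  cfg <- list(n_sites = as.integer(n_sites), period = as.integer(period),
              lambda = lambda, gamma = gamma, epsilon = epsilon,
              resp_base = resp_base, resp_temp_sens = resp_temp_sens, c0 = c0,
              disturbance_prob = disturbance_prob,
              disturbance_drop = disturbance_drop, recovery_tau = recovery_tau,
              gap_rate_reflectance = gap_rate_reflectance,
              tropical_gap_factor = tropical_gap_factor,
              qc_alpha = qc_alpha, qc_beta = qc_beta, noise = noise,
              window_years = as.integer(window_years),
              window_period = as.integer(window_period),
              aux_start_year = as.integer(aux_start_year),
              pft_weights = pft_weights, climate_weights = climate_weights,
              hemisphere_north_prob = hemisphere_north_prob,
              allow_infinite_memory = allow_infinite_memory,
              master_seed = as.integer(master_seed))
  class(cfg) <- "fm_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!is.finite(cfg$n_sites) || cfg$n_sites < 1)
    stop_config("n_sites", "must be a positive integer")
  if (length(cfg$period) != 2 || diff(cfg$period) + 1 < 5)
    stop_config("period", "must span at least 5 years")
  if (cfg$lambda < 0 || cfg$lambda > 1)
    stop_config("lambda", "must lie in [0, 1]")
  if (cfg$lambda == 0 && !cfg$allow_infinite_memory)
    stop_config("lambda",
                "0 implies an infinite-memory pool; set allow_infinite_memory = TRUE to request it")
  for (f in c("disturbance_prob", "gap_rate_reflectance", "disturbance_drop",
              "hemisphere_north_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config(f, "must be a probability in [0, 1]")
  if (cfg$qc_alpha <= 0 || cfg$qc_beta <= 0)
    stop_config("qc_alpha/qc_beta", "Beta parameters must be positive")
  if (cfg$recovery_tau <= 0)
    stop_config("recovery_tau", "must be positive")
  if (any(cfg$window_years < 1) || cfg$window_years[1] > cfg$window_years[2])
    stop_config("window_years", "must be an increasing pair of positive years")
  wp <- cfg$window_period
  if (wp[1] < cfg$period[1] || wp[2] > cfg$period[2])
    stop_config("window_period", "must lie within `period`")
  if (any(unlist(cfg$noise) < 0))
    stop_config("noise", "noise scales must be non-negative")
  invisible(cfg)
}

#' Canonical 40-site study fixture
#'
#' The scaled-down configuration used throughout the experiments and tests:
#' 40 sites on 20-year panels (1996--2015) with pool decay
#' `lambda = 0.2` (pool half-life about 3.1 months), disturbances on, and no
#' reflectance gaps so that the sequence-model experiments are decoupled
#' from the gap-filling stage (which is exercised separately on gappy
#' configurations).
#'
#' @param master_seed master seed.
#' @param ... overrides passed on to [generator_config()].
#' @return an `fm_config`.
#' @export
fixture_config <- function(master_seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_sites = 40L, period = c(1996L, 2015L),
         gap_rate_reflectance = 0, master_seed = master_seed),
    list(...))
  do.call(generator_config, args)
}
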