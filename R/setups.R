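SETUP_NAMES <- c("LSTM", "LSTM_perm", "LSTM_msc", "LSTM_annual", "RF")

#' Mean seasonal cycle of a monthly series
#'
#' The value for calendar month m is the mean of all observations of month
#' m across the years of the record.
#'
#' @param values numeric monthly values.
#' @param months calendar months (1--12) aligned with `values`.
#' @return named numeric vector of 12 calendar-month means.
#' @export
compute_msc <- function(values, months) {
  if (length(values) < 12) stop("need at least 12 months to compute an MSC")
  out <- vapply(1:12, function(m) {
    v <- values[months == m & !is.na(values)]
    if (!length(v)) stop("calendar month ", m, " entirely missing")
    mean(v)
  }, 0)
  names(out) <- 1:12
  out
}

# 12 x D table of column MSCs for a sample's predictor matrix
msc_table <- function(sample) {
  apply(sample$X, 2, function(col) compute_msc(col, sample$month))
}

band_idx <- function() match(BANDS, PREDICTORS)

#' Factorial predictor ablations
#'
#' Materialize the model set-ups as predictor transformations over a common
#' sample list. `make_msc_variant()` replaces each reflectance band by its
#' mean seasonal cycle tiled over the years; `make_annual_variant()` by its
#' calendar-year mean (constant within year, varying across years); both
#' leave the four climate columns untouched. `make_permuted_variant()`
#' applies one random permutation of timestep indices jointly to the
#' predictor rows, target, mask and time index within each site, destroying
#' the temporal order while exactly preserving the per-site multiset of
#' (predictors, target) pairs.
#'
#' @param samples list of sequence samples.
#' @return transformed sample list with attribute `setup`.
#' @export
make_msc_variant <- function(samples) {
  bi <- band_idx()
  out <- lapply(samples, function(s) {
    for (j in bi) {
      msc <- compute_msc(s$X[, j], s$month)
      s$X[, j] <- msc[s$month]
    }
    s
  })
  structure(out, setup = "LSTM_msc")
}

#' @rdname make_msc_variant
#' @export
make_annual_variant <- function(samples) {
  bi <- band_idx()
  out <- lapply(samples, function(s) {
    for (j in bi) {
      ym <- tapply(s$X[, j], s$year, mean)
      s$X[, j] <- ym[as.character(s$year)]
    }
    s
  })
  structure(out, setup = "LSTM_annual")
}

#' @rdname make_msc_variant
#' @param seed integer seed; the permutation is seeded per site.
#' @export
make_permuted_variant <- function(samples, seed) {
  out <- lapply(samples, function(s) {
    perm <- with_seed(derive_seed(seed, "perm", s$site_id),
                      sample(length(s$y)))
    s$X <- s$X[perm, , drop = FALSE]
    s$y <- s$y[perm]
    s$mask <- s$mask[perm]
    s$year <- s$year[perm]
    s$month <- s$month[perm]
    s
  })
  structure(out, setup = "LSTM_perm")
}

#' @rdname make_msc_variant
#' @param name one of `"LSTM", "LSTM_perm", "LSTM_msc", "LSTM_annual", "RF"`.
#' @export
make_setup <- function(samples, name, seed = 1) {
  name <- match.arg(name, SETUP_NAMES)
  switch(name,
         LSTM = structure(samples, setup = "LSTM"),
         RF = structure(samples, setup = "RF"),
         LSTM_perm = make_permuted_variant(samples, seed),
         LSTM_msc = make_msc_variant(samples),
         LSTM_annual = make_annual_variant(samples))
}

#' Counterfactual altered-forcings inputs
#'
#' For predicting a target calendar year i, the predictor values of years
#' i-1 ... i-`n_years` are replaced by their mean seasonal cycle
#' (reflectance bands, climate variables, or both, per `scenario`); earlier
#' years and year i itself keep their actual values. With `n_years = 0`
#' the sample is returned unchanged.
#'
#' @param sample one sequence sample (raw scale).
#' @param target_year calendar year whose predictions will be extracted.
#' @param n_years how many preceding years to alter (0--5).
#' @param scenario `"all"`, `"climate_only"` or `"reflectance_only"`.
#' @param msc optional precomputed 12 x D MSC table of the sample.
#' @return the sample with altered predictor rows.
#' @export
make_altered_forcings <- function(sample, target_year, n_years,
                                  scenario = c("all", "climate_only",
                                               "reflectance_only"),
                                  msc = NULL) {
  scenario <- match.arg(scenario)
  if (n_years == 0) return(sample)
  if (target_year - n_years < min(sample$year))
    stop("altered years extend before the panel start")
  msc <- msc %||% msc_table(sample)
  cols <- switch(scenario,
                 all = seq_along(PREDICTORS),
                 climate_only = match(CLIMVARS, PREDICTORS),
                 reflectance_only = band_idx())
  rows <- sample$year >= target_year - n_years & sample$year < target_year
  sample$X[rows, cols] <- msc[sample$month[rows], cols]
  sample
}
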