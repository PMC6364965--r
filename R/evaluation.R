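#' Nash-Sutcliffe efficiency
#'
#' `1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)`; 1 is a perfect
#' model, 0 no better than the observation mean.
#'
#' @param obs,pred numeric vectors of equal length (>= 2).
#' @return scalar in (-Inf, 1].
#' @export
nse <- function(obs, pred) {
  if (length(obs) < 2 || length(obs) != length(pred))
    stop("nse needs two equal-length vectors with >= 2 values")
  den <- sum((obs - mean(obs))^2)
  if (den <= 0) stop("nse undefined: observations have zero variance")
  1 - sum((pred - obs)^2) / den
}

#' Evaluation metric suite
#'
#' NSE, squared Pearson correlation (R2), root mean squared error and mean
#' absolute error.
#'
#' @inheritParams nse
#' @return named list `nse, r2, rmse, mae`.
#' @export
metric_suite <- function(obs, pred) {
  list(nse = nse(obs, pred), r2 = cor(obs, pred)^2,
       rmse = sqrt(mean((pred - obs)^2)), mae = mean(abs(pred - obs)))
}

#' Years with complete monthly coverage
#'
#' A year is complete iff all 12 calendar months are observed.
#'
#' @param year,month time index vectors.
#' @param mask logical observation mask (defaults to all TRUE).
#' @return sorted integer vector of complete years.
#' @export
complete_years <- function(year, month, mask = rep(TRUE, length(year))) {
  y <- year[mask]; m <- month[mask]
  cnt <- tapply(m, y, function(v) length(unique(v)))
  sort(as.integer(names(cnt)[cnt == 12]))
}

#' Align calendar months across hemispheres
#'
#' Months of southern-hemisphere sites are shifted by six so that their
#' seasonal cycle lines up with northern sites; applying the shift twice
#' returns the original month.
#'
#' @param month integer months 1--12.
#' @param latitude site latitude in degrees.
#' @return aligned months in 1--12.
#' @export
hemisphere_align <- function(month, latitude) {
  south <- rep_len(latitude < 0, length(month))
  ifelse(south, (month + 5) %% 12 + 1, month)
}

#' Four-scale decomposition of a prediction table
#'
#' Splits aligned (observation, prediction) pairs into the four variability
#' scales: the raw monthly series (`seasonal_cycle`); per-site seasonal
#' anomalies (monthly value minus that site's calendar-month mean, each of
#' obs and pred centered on its own means); interannual anomalies (annual
#' mean over complete years minus the site mean of those annual means); and
#' across-site variability (one pair of site means per site). Anomalies are
#' computed only for sites with at least `min_years` complete years of
#' observations; other sites are listed in `excluded`.
#'
#' @param table data.frame with `site_id, year, month, obs` and a
#'   prediction column.
#' @param pred_col name of the prediction column (default `"pred"`).
#' @param min_years complete-year threshold for the anomaly scales.
#' @return list of four data.frames (`obs`, `pred`, `site_id`, ...) plus
#'   `excluded` (site ids failing the complete-year filter).
#' @export
decompose <- function(table, pred_col = "pred", min_years = 3) {
  tab <- data.frame(site_id = table$site_id, year = table$year,
                    month = table$month, obs = table$obs,
                    pred = table[[pred_col]], stringsAsFactors = FALSE)
  by_site <- split(tab, tab$site_id)

  seasonal_cycle <- tab

  eligible <- vapply(by_site, function(d)
    length(complete_years(d$year, d$month)) >= min_years, TRUE)
  elig_sites <- names(by_site)[eligible]

  seas_anom <- do.call(rbind, lapply(by_site[eligible], function(d) {
    mo <- ave(d$obs, d$month)
    mp <- ave(d$pred, d$month)
    data.frame(site_id = d$site_id, year = d$year, month = d$month,
               obs = d$obs - mo, pred = d$pred - mp)
  }))

  ia_anom <- do.call(rbind, lapply(by_site[eligible], function(d) {
    cy <- complete_years(d$year, d$month)
    d <- d[d$year %in% cy, ]
    ao <- tapply(d$obs, d$year, mean)
    ap <- tapply(d$pred, d$year, mean)
    data.frame(site_id = d$site_id[1], year = as.integer(names(ao)),
               obs = as.numeric(ao - mean(ao)),
               pred = as.numeric(ap - mean(ap)))
  }))

  across_site <- do.call(rbind, lapply(by_site, function(d)
    data.frame(site_id = d$site_id[1], obs = mean(d$obs),
               pred = mean(d$pred))))

  list(seasonal_cycle = seasonal_cycle,
       seasonal_anomalies = seas_anom,
       interannual_anomalies = ia_anom,
       across_site = across_site,
       excluded = setdiff(names(by_site), elig_sites))
}

#' Seasonal curve of site-centered residuals
#'
#' Residual per site i and month j is
#' `(obs_ij - mean(obs_i)) - (pred_ij - mean(pred_i))`, i.e. both series
#' are centered per site so constant site offsets cancel. Residuals are
#' averaged by hemisphere-aligned calendar month across the sites of a
#' forest type; with `member_preds`, the curve is computed per ensemble
#' member and the spread across members reported.
#'
#' @param table prediction table (`site_id, year, month, obs, pred`).
#' @param sites site table (for latitude and pft).
#' @param forest_type optional pft filter (e.g. `"deciduous"`).
#' @param member_preds optional rows x members matrix aligned with `table`.
#' @return data.frame `month, resid_mean, resid_sd, n_sites`.
#' @export
residual_seasonal_curve <- function(table, sites, forest_type = NULL,
                                    member_preds = NULL) {
  i <- match(table$site_id, sites$site_id)
  tab <- cbind(table, latitude = sites$latitude[i], pft = sites$pft[i])
  if (!is.null(forest_type)) {
    keep <- tab$pft == forest_type
    tab <- tab[keep, ]
    member_preds <- if (!is.null(member_preds))
      member_preds[keep, , drop = FALSE]
  }
  tab$month_aligned <- hemisphere_align(tab$month, tab$latitude)
  one_curve <- function(pred) {
    r <- (tab$obs - ave(tab$obs, tab$site_id)) -
         (pred - ave(pred, tab$site_id))
    tapply(r, factor(tab$month_aligned, levels = 1:12), mean)
  }
  if (is.null(member_preds)) {
    cm <- one_curve(tab$pred)
    csd <- rep(0, 12)
  } else {
    curves <- sapply(seq_len(ncol(member_preds)),
                     function(m) one_curve(member_preds[, m]))
    cm <- rowMeans(curves)
    csd <- apply(curves, 1, sd)
  }
  data.frame(month = 1:12, resid_mean = as.numeric(cm),
             resid_sd = as.numeric(csd),
             n_sites = length(unique(tab$site_id)))
}

safe_metrics <- function(obs, pred) {
  tryCatch(metric_suite(obs, pred),
           error = function(e) list(nse = NA_real_, r2 = NA_real_,
                                    rmse = NA_real_, mae = NA_real_))
}

metric_row <- function(vals, metric) {
  v <- vapply(vals, function(x) x[[metric]], 0)
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
}

#' Stratified multi-scale evaluation report
#'
#' Computes the metric suite for every variability scale, overall and per
#' stratum (plant functional type, climate class, age class). Metrics are
#' computed per ensemble member and reported as member mean and sd (the
#' primary summary), alongside the metrics of the ensemble-mean prediction.
#' Strata with no sites passing the complete-year filter get `NA` at the
#' anomaly scales rather than a number.
#'
#' @param cv an `fm_cv` object (or a compatible list with `predictions`
#'   and `member_preds`).
#' @param sites site table.
#' @param by stratification columns of `sites` (besides `"all"`).
#' @param min_years complete-year threshold for anomalies.
#' @return long data.frame: setup, scale, stratum_type, stratum, metric
#'   mean/sd over members, value for the mean prediction, and sizes.
#' @export
stratified_report <- function(cv, sites,
                              by = c("pft", "climate_class", "age_class"),
                              min_years = 3) {
  tab <- cv$predictions
  mp <- cv$member_preds
  strata <- list(all = list(all = sites$site_id))
  for (b in by)
    strata[[b]] <- split(sites$site_id, sites[[b]])
  out <- list()
  for (stype in names(strata)) for (sname in names(strata[[stype]])) {
    ids <- strata[[stype]][[sname]]
    keep <- tab$site_id %in% ids
    if (!any(keep)) next
    sub <- tab[keep, , drop = FALSE]
    subm <- mp[keep, , drop = FALSE]
    dec_mean <- decompose(sub, min_years = min_years)
    dec_members <- lapply(seq_len(ncol(subm)), function(m) {
      s2 <- sub; s2$pred <- subm[, m]
      decompose(s2, min_years = min_years)
    })
    for (scale in c("seasonal_cycle", "seasonal_anomalies",
                    "interannual_anomalies", "across_site")) {
      dm <- dec_mean[[scale]]
      if (is.null(dm) || nrow(dm) < 2) {
        vals_mean <- list(nse = NA_real_, r2 = NA_real_, rmse = NA_real_,
                          mae = NA_real_)
        per_member <- NULL
      } else {
        vals_mean <- safe_metrics(dm$obs, dm$pred)
        per_member <- lapply(dec_members, function(d)
          safe_metrics(d[[scale]]$obs, d[[scale]]$pred))
      }
      for (metric in c("nse", "r2", "rmse", "mae")) {
        ms <- if (is.null(per_member)) c(mean = NA_real_, sd = NA_real_)
              else metric_row(per_member, metric)
        out[[length(out) + 1]] <- data.frame(
          setup = cv$setup %||% "model", scale = scale,
          stratum_type = stype, stratum = sname, metric = metric,
          member_mean = unname(ms["mean"]), member_sd = unname(ms["sd"]),
          of_mean_pred = vals_mean[[metric]],
          n_sites = length(unique(dm$site_id %||% character(0))),
          n_rows = if (is.null(dm)) 0L else nrow(dm))
      }
    }
  }
  do.call(rbind, out)
}
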