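#' Monthly NEE quality filter
#'
#' Retains a monthly NEE value only when its quality fraction is strictly
#' greater than `threshold` (default 0.8: months with more than 80% original
#' or good-quality gap-filled data). Idempotent.
#'
#' @param panel long panel data.frame with `nee` and `nee_quality`.
#' @param threshold quality threshold in (0, 1].
#' @return the panel with failing months' NEE set to `NA`; the number of
#'   retained NEE months is in `attr(, "n_retained")`.
#' @export
qc_filter <- function(panel, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1)
    stop_config("threshold", "must lie in (0, 1]")
  if (is.null(panel$nee_quality)) stop("panel has no `nee_quality` column")
  drop <- !is.na(panel$nee) &
    (is.na(panel$nee_quality) | panel$nee_quality <= threshold)
  panel$nee[drop] <- NA_real_
  attr(panel, "n_retained") <- sum(!is.na(panel$nee))
  panel
}

rf_fit <- function(x, y, seed, num.trees = 200) {
  d <- cbind(x, .target = y)
  ranger::ranger(dependent.variable.name = ".target", data = d,
                 num.trees = num.trees, seed = seed, num.threads = 1,
                 respect.unordered.factors = "order")
}

# NSE of a random forest trained on 70% of the rows, scored on the held-out
# 30% — the skill bookkeeping attached to every gap-fill model
rf_fit_score <- function(x, y, seed) {
  n <- nrow(x)
  if (n < 10) return(NA_real_)
  held <- with_seed(derive_seed(seed, "score"),
                    sort(sample(n, max(1, round(0.3 * n)))))
  fit <- rf_fit(x[-held, , drop = FALSE], y[-held], seed)
  tryCatch(nse(y[held], rf_predict(fit, x[held, , drop = FALSE])),
           error = function(e) NA_real_)
}

rf_predict <- function(model, x) {
  predict(model, data = x, num.threads = 1)$predictions
}

#' Shadow-feature selection
#'
#' A Boruta-style procedure: every candidate column is duplicated as a
#' within-column permutation ("shadow"); a random-forest impurity importance
#' is computed over candidates plus shadows, and a candidate scores a hit in
#' a repeat when its importance exceeds the maximum shadow importance.
#' Candidates with hits in at least `frac` of `n_repeats` repeats are
#' selected. If nothing is significant the single top-ranked candidate is
#' returned, flagged via `attr(, "none_significant")`.
#'
#' @param candidates data.frame of candidate predictors.
#' @param target numeric response.
#' @param seed integer seed.
#' @param n_repeats,frac repeats and required hit fraction.
#' @param num.trees trees per forest.
#' @return character vector of selected column names (candidate column
#'   order), with attributes `hits` and `none_significant`.
#' @export
select_features <- function(candidates, target, seed, n_repeats = 20,
                            frac = 0.8, num.trees = 100) {
  ok <- complete.cases(candidates) & !is.na(target)
  if (sum(ok) < 50)
    stop("insufficient data: need >= 50 complete rows, have ", sum(ok))
  x <- candidates[ok, , drop = FALSE]
  y <- target[ok]
  p <- ncol(x)
  hits <- setNames(numeric(p), names(x))
  imp_sum <- setNames(numeric(p), names(x))
  for (r in seq_len(n_repeats)) {
    shadows <- with_seed(derive_seed(seed, "shadow", r),
                         as.data.frame(lapply(x, sample)))
    names(shadows) <- paste0(".shadow_", names(x))
    fit <- ranger::ranger(x = cbind(x, shadows), y = y,
                          num.trees = num.trees, importance = "impurity",
                          seed = derive_seed(seed, "rf", r), num.threads = 1)
    imp <- fit$variable.importance
    thr <- max(imp[paste0(".shadow_", names(x))])
    hits <- hits + (imp[names(x)] > thr)
    imp_sum <- imp_sum + imp[names(x)]
  }
  sel <- names(x)[hits >= frac * n_repeats]
  none <- length(sel) == 0
  if (none) sel <- names(x)[which.max(imp_sum)]
  structure(sel, hits = hits / n_repeats, none_significant = none)
}

src_cols <- function(panel) {
  for (b in BANDS) {
    sc <- paste0("src_", b)
    if (is.null(panel[[sc]]))
      panel[[sc]] <- ifelse(is.na(panel[[b]]), "missing", "observed")
  }
  panel
}

#' Stage-1 reflectance gap-filling from auxiliary bands
#'
#' Fills reflectance gaps inside the auxiliary-table coverage period with a
#' per-site, per-band random forest trained on months where both the target
#' band and the auxiliary bands are observed (emulating gap-filling from a
#' co-located coarser-resolution satellite record). Falls back to a global
#' per-band model for sites without training overlap; a band with no
#' overlap anywhere is skipped with a warning. Observed values are never
#' overwritten; fills are flagged `src_<band> = "stage1"`.
#'
#' @param panel long multi-site panel with `obs_<band>` flags.
#' @param aux long auxiliary table (`site_id, year, month, aux_*`).
#' @param seed integer seed.
#' @return the panel with stage-1 fills, `src_*` provenance columns, and
#'   per-band 70/30 held-out NSE of the fill models in
#'   `attr(, "fit_scores")`.
#' @export
gapfill_stage1 <- function(panel, aux, seed) {
  panel <- src_cols(panel)
  auxvars <- grep("^aux_", names(aux), value = TRUE)
  key <- function(d) paste(d$site_id, d$year, d$month)
  m <- match(key(panel), key(aux))
  auxm <- aux[m, auxvars, drop = FALSE]
  covered <- !is.na(m) & complete.cases(auxm)
  fit_scores <- setNames(rep(NA_real_, length(BANDS)), BANDS)
  for (b in BANDS) {
    obs <- !is.na(panel[[b]])
    train <- obs & covered
    fill <- !obs & covered
    if (!any(fill)) next
    if (!any(train)) {
      warning("stage 1 skipped for band `", b, "`: no overlap with auxiliaries")
      next
    }
    global <- rf_fit(auxm[train, , drop = FALSE], panel[[b]][train],
                     derive_seed(seed, "s1", b))
    fit_scores[b] <- rf_fit_score(auxm[train, , drop = FALSE],
                                  panel[[b]][train],
                                  derive_seed(seed, "s1", b))
    for (sid in unique(panel$site_id[fill])) {
      si <- panel$site_id == sid
      tr_s <- train & si
      fi_s <- fill & si
      model <- if (sum(tr_s) >= 12)
        rf_fit(auxm[tr_s, , drop = FALSE], panel[[b]][tr_s],
               derive_seed(seed, "s1", b, sid)) else global
      panel[[b]][fi_s] <- rf_predict(model, auxm[fi_s, , drop = FALSE])
      panel[[paste0("src_", b)]][fi_s] <- "stage1"
    }
  }
  attr(panel, "fit_scores") <- fit_scores
  panel
}

stage2_design <- function(panel, sites) {
  i <- match(panel$site_id, sites$site_id)
  x <- data.frame(tair = panel$tair, precip = panel$precip, rg = panel$rg,
                  vpd = panel$vpd, rpot = panel$rpot,
                  latitude = sites$latitude[i],
                  month_sin = sin(2 * pi * panel$month / 12),
                  month_cos = cos(2 * pi * panel$month / 12))
  for (p in unique(sites$pft)) x[[paste0("pft_", p)]] <-
      as.numeric(sites$pft[i] == p)
  x
}

#' Stage-2 reflectance gap-filling from climate and site descriptors
#'
#' Fills every remaining reflectance gap over the full panel period with a
#' global per-band random forest on climate (`tair, precip, rg, vpd, rpot`),
#' latitude, cyclic month-of-year encoding and one-hot plant functional
#' type. Fills are flagged `src_<band> = "stage2"`; afterwards no
#' reflectance is missing.
#'
#' @param panel long panel (after [gapfill_stage1()], or directly).
#' @param sites site table.
#' @param seed integer seed.
#' @return the fully filled panel, with per-band 70/30 held-out NSE of the
#'   fill models in `attr(, "fit_scores")`.
#' @export
gapfill_stage2 <- function(panel, sites, seed) {
  panel <- src_cols(panel)
  x <- stage2_design(panel, sites)
  fit_scores <- setNames(rep(NA_real_, length(BANDS)), BANDS)
  for (b in BANDS) {
    obs <- !is.na(panel[[b]])
    if (!any(obs))
      stop("stage 2 cannot fill band `", b, "`: no observed month to train on")
    if (all(obs)) next
    model <- rf_fit(x[obs, , drop = FALSE], panel[[b]][obs],
                    derive_seed(seed, "s2", b))
    fit_scores[b] <- rf_fit_score(x[obs, , drop = FALSE], panel[[b]][obs],
                                  derive_seed(seed, "s2", b))
    panel[[b]][!obs] <- rf_predict(model, x[!obs, , drop = FALSE])
    panel[[paste0("src_", b)]][!obs] <- "stage2"
  }
  attr(panel, "fit_scores") <- fit_scores
  panel
}

DOWNSCALE_FAMILIES <- c("linear", "kernel_ridge", "neighbor_mean")

fit_downscale_family <- function(family, xtr, ytr) {
  switch(family,
         linear = {
           fit <- lm(y ~ ., data = cbind(xtr, y = ytr))
           function(x) as.numeric(predict(fit, x))
         },
         kernel_ridge = {
           # capture.output: gausspr prints its sigma estimation note
           utils::capture.output(
             fit <- kernlab::gausspr(as.matrix(xtr), ytr, kernel = "rbfdot",
                                     var = 0.01))
           function(x) as.numeric(kernlab::predict(fit, as.matrix(x), type = "response"))
         },
         neighbor_mean = function(x) rowMeans(x),
         stop("unknown downscale family: ", family))
}

#' Down-scale a site climate series from neighboring grid cells
#'
#' Candidate statistical families (linear regression, kernel ridge via
#' Gaussian-process regression, nearest-neighbor mean) are fit on the
#' overlap between the gappy site series and the three neighbor series;
#' the family with the highest Nash-Sutcliffe efficiency on a held-out 20%
#' of overlap months is selected (lowest RMSE for precipitation) and used
#' to fill the gaps. Family candidates are scored in a fixed canonical
#' order, so the selection does not depend on the order they are listed.
#'
#' @param site_obs numeric series with `NA` gaps.
#' @param neighbors matrix/data.frame of three co-variate series.
#' @param variable one of `"tair", "rg", "vpd", "precip"`; precipitation
#'   switches the selection metric to RMSE.
#' @param families candidate family names.
#' @param seed integer seed for the held-out split.
#' @return list `filled` (series with gaps replaced), `selection` (scores,
#'   chosen family, `low_skill` flag), or a pass-through with a warning when
#'   the overlap is shorter than 24 months.
#' @export
downscale_climate <- function(site_obs, neighbors, variable = "tair",
                              families = DOWNSCALE_FAMILIES, seed = 1) {
  families <- DOWNSCALE_FAMILIES[DOWNSCALE_FAMILIES %in% families]
  x <- as.data.frame(neighbors)
  names(x) <- paste0("n", seq_len(ncol(x)))
  overlap <- which(!is.na(site_obs) & complete.cases(x))
  if (length(overlap) < 24) {
    warning("overlap shorter than 24 months; returning series unfilled")
    return(list(filled = site_obs, selection = NULL))
  }
  held <- with_seed(derive_seed(seed, "holdout"),
                    sort(sample(overlap, max(1, round(0.2 * length(overlap))))))
  tr <- setdiff(overlap, held)
  use_rmse <- identical(variable, "precip")
  scores <- setNames(numeric(length(families)), families)
  preds <- list()
  for (fam in families) {
    f <- fit_downscale_family(fam, x[tr, , drop = FALSE], site_obs[tr])
    ph <- f(x[held, , drop = FALSE])
    scores[fam] <- if (use_rmse) -sqrt(mean((ph - site_obs[held])^2))
                   else nse(site_obs[held], ph)
    preds[[fam]] <- f
  }
  chosen <- families[which.max(scores)]  # ties: first in canonical order
  gaps <- which(is.na(site_obs) & complete.cases(x))
  filled <- site_obs
  if (length(gaps)) filled[gaps] <- preds[[chosen]](x[gaps, , drop = FALSE])
  list(filled = filled,
       selection = list(variable = variable,
                        metric = if (use_rmse) "rmse" else "nse",
                        candidate_scores = if (use_rmse) -scores else scores,
                        chosen_family = chosen,
                        low_skill = !use_rmse && max(scores) <= 0))
}
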