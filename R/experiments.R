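#' Assign entire sites to cross-validation folds
#'
#' Random balanced partition of sites into K folds (sizes differ by at most
#' one); a site's months never split across folds. Optional stratification
#' keeps class proportions roughly even across folds (off by default).
#'
#' @param sites site table.
#' @param K number of folds.
#' @param seed integer seed.
#' @param stratify_by optional column name of `sites` (e.g.
#'   `"climate_class"`).
#' @return data.frame `site_id, fold`.
#' @export
assign_folds <- function(sites, K = 10, seed = 1, stratify_by = NULL) {
  n <- nrow(sites)
  if (K < 2 || K > n) stop("K must lie in [2, number of sites]")
  fold <- integer(n)
  if (is.null(stratify_by)) {
    sizes <- rep(n %/% K, K) + c(rep(1, n %% K), rep(0, K - n %% K))
    ord <- with_seed(derive_seed(seed, "folds"), sample(n))
    fold[ord] <- rep(seq_len(K), times = sizes)
  } else {
    strata <- sites[[stratify_by]]
    nxt <- with_seed(derive_seed(seed, "folds"), {
      f <- integer(n)
      start <- 0
      for (g in unique(strata)) {
        idx <- sample(which(strata == g))
        f[idx] <- (start + seq_along(idx) - 1) %% K + 1
        start <- start + length(idx)
      }
      f
    })
    fold <- nxt
  }
  data.frame(site_id = sites$site_id, fold = fold, stringsAsFactors = FALSE)
}

#' Entire-site k-fold cross-validation of one model set-up
#'
#' For each fold: fit the standardizer, (optionally) run the hyperparameter
#' grid search, and train the ensemble on the other K-1 folds; predict the
#' held-out fold. Held-out predictions therefore cover every site exactly
#' once, and no site ever contributes to the model that predicts it (the
#' provenance table records the training sites of every fold).
#'
#' @param samples sequence samples of the chosen set-up variant (raw scale).
#' @param sites site table.
#' @param folds an [assign_folds()] table.
#' @param model `"lstm"` or `"rf"`.
#' @param hp hyperparameters (ignored when `grid` is given).
#' @param grid optional list of hyperparameters for a nested per-fold grid
#'   search.
#' @param n_members ensemble size.
#' @param seed integer seed.
#' @param eval_frac early-stopping split fraction.
#' @param setup label stored in the prediction table (defaults to the
#'   variant's `setup` attribute).
#' @return list of class `fm_cv`: `predictions` (one row per observed
#'   site-month: `site_id, year, month, obs, pred, pred_sd, fold, setup`),
#'   `member_preds` (rows x members matrix), `models` (per fold:
#'   standardizer, ensemble, hyperparameters, training sites), `folds`,
#'   `provenance`.
#' @export
run_cross_validation <- function(samples, sites, folds, model = c("lstm", "rf"),
                                 hp = hyperparams(), grid = NULL,
                                 n_members = 5, seed = 1, eval_frac = 0.2,
                                 setup = NULL) {
  model <- match.arg(model)
  setup <- setup %||% attr(samples, "setup") %||% toupper(model)
  sid <- vapply(samples, `[[`, "", "site_id")
  stopifnot(identical(sort(sid), sort(folds$site_id)))
  K <- max(folds$fold)
  rows <- list(); members <- list(); models <- vector("list", K)
  prov <- list()
  for (k in seq_len(K)) {
    test_ids <- folds$site_id[folds$fold == k]
    tr <- samples[!(sid %in% test_ids)]
    te <- samples[sid %in% test_ids]
    prov[[k]] <- data.frame(fold = k, test_site = rep(test_ids,
                                                      each = 1),
                            train_sites = paste(sort(setdiff(sid, test_ids)),
                                                collapse = ";"))
    if (!any(unlist(lapply(te, `[[`, "mask")))) {
      message("fold ", k, " has no observed test months; skipped")
      next
    }
    std <- fit_standardizer(tr)
    tr_s <- apply_standardizer(tr, std)
    te_s <- apply_standardizer(te, std)
    if (model == "lstm") {
      hp_k <- if (!is.null(grid))
        grid_search(tr_s, grid, seed = derive_seed(seed, "grid", k),
                    eval_frac = eval_frac) else hp
      ens <- fit_ensemble(tr_s, hp_k, n_members,
                          seed = derive_seed(seed, "fold", k),
                          eval_frac = eval_frac)
      pr <- predict_ensemble(ens, te_s)          # T x S x M, standardized
      pr <- invert_target(std, pr)
      models[[k]] <- list(standardizer = std, ensemble = ens, hp = hp_k,
                          train_sites = setdiff(sid, test_ids))
    } else {
      d <- static_rows(tr_s)
      fits <- lapply(seq_len(n_members), function(m)
        train_static_baseline(d$X, d$y, seed = derive_seed(seed, "rf", k, m)))
      b <- samples_to_batch(te_s)
      T_ <- dim(b$X)[1]
      pr <- array(NA_real_, dim = c(T_, length(te), n_members))
      flat <- do.call(rbind, lapply(te_s, `[[`, "X"))
      for (m in seq_len(n_members)) {
        p <- predict(fits[[m]], flat)
        pr[, , m] <- matrix(p, nrow = T_)
      }
      pr <- invert_target(std, pr)
      models[[k]] <- list(standardizer = std, fits = fits,
                          train_sites = setdiff(sid, test_ids))
    }
    for (j in seq_along(te)) {
      s <- te[[j]]
      w <- which(s$mask)
      if (!length(w)) next
      pm <- pr[w, j, , drop = FALSE]
      pm <- matrix(pm, nrow = length(w))
      rows[[length(rows) + 1]] <- data.frame(
        site_id = s$site_id, year = s$year[w], month = s$month[w],
        obs = s$y[w], pred = rowMeans(pm),
        pred_sd = apply(pm, 1, sd), fold = k, setup = setup,
        stringsAsFactors = FALSE)
      members[[length(members) + 1]] <- pm
    }
  }
  structure(list(predictions = do.call(rbind, rows),
                 member_preds = do.call(rbind, members),
                 models = models, folds = folds,
                 provenance = do.call(rbind, prov), setup = setup,
                 model = model, n_members = n_members),
            class = "fm_cv")
}

pft_group_of <- function(pft) ifelse(pft %in% c("deciduous", "evergreen"),
                                     pft, "other")

#' Altered-forcings counterfactual experiment
#'
#' For every site, uses the LSTM ensemble of the fold in which the site was
#' held out, and predicts the site's panel after replacing the predictors
#' of the `n` years preceding each target year by their mean seasonal
#' cycle. Reports the mean absolute difference between altered and
#' unaltered monthly predictions, aggregated per hemisphere-aligned
#' calendar month and per forest type, with the ensemble spread.
#'
#' Target years are restricted to those with `max(n_years)` full preceding
#' years in the panel, so every `n` is evaluated on the same months.
#'
#' @param cv an `fm_cv` from a `"lstm"` run.
#' @param samples the raw-scale samples the CV ran on.
#' @param sites site table.
#' @param n_years_list numbers of altered years (default 1:5).
#' @param scenarios subset of `"all", "climate_only", "reflectance_only"`.
#' @return list: `curves` (scenario, n, pft_group, aligned month, mean and
#'   sd over members of the mean absolute deviation), `by_n` (deviation
#'   per scenario and n), `noise_floor` (mean across months of the
#'   between-member sd of unaltered predictions).
#' @export
run_altered_forcings <- function(cv, samples, sites, n_years_list = 1:5,
                                 scenarios = "all") {
  if (cv$model != "lstm") stop("altered forcings needs a trained LSTM cv")
  sid <- vapply(samples, `[[`, "", "site_id")
  max_n <- max(n_years_list)
  devs <- list(); floors <- numeric(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    k <- cv$folds$fold[cv$folds$site_id == s$site_id]
    mod <- cv$models[[k]]
    if (is.null(mod)) next
    std <- mod$standardizer
    msc <- msc_table(s)
    years <- sort(unique(s$year))
    targets <- years[years - max_n >= min(years)]
    if (!length(targets)) next
    # build the batch of altered series: one slice per (scenario, n, target)
    specs <- expand.grid(scenario = scenarios, n = n_years_list,
                         target = targets, stringsAsFactors = FALSE)
    T_ <- nrow(s$X); D <- ncol(s$X)
    Xb <- array(0, dim = c(T_, D, nrow(specs) + 1))
    std_X <- function(X) sweep(sweep(X, 2, std$x_mean), 2, std$x_sd, "/")
    Xb[, , 1] <- std_X(s$X)
    for (v in seq_len(nrow(specs))) {
      alt <- make_altered_forcings(s, specs$target[v], specs$n[v],
                                   specs$scenario[v], msc = msc)
      Xb[, , v + 1] <- std_X(alt$X)
    }
    M <- length(mod$ensemble$members)
    base_mat <- matrix(NA_real_, T_, M)
    dev_rows <- list()
    for (m in seq_len(M)) {
      p <- lstm_forward(Xb, mod$ensemble$members[[m]]$weights)
      p <- invert_target(std, p)
      base_mat[, m] <- p[, 1]
      for (v in seq_len(nrow(specs))) {
        w <- which(s$year == specs$target[v])
        dev_rows[[length(dev_rows) + 1]] <- data.frame(
          site_id = s$site_id, pft = s$pft, latitude = s$latitude,
          scenario = specs$scenario[v], n = specs$n[v],
          target_year = specs$target[v], month = s$month[w], member = m,
          absdev = abs(p[w, v + 1] - p[w, 1]))
      }
    }
    floors[s$site_id] <- mean(apply(base_mat, 1, sd))
    devs[[i]] <- do.call(rbind, dev_rows)
  }
  dev <- do.call(rbind, devs)
  if (is.null(dev)) stop("no site had enough preceding years for max(n_years)")
  dev$month_aligned <- hemisphere_align(dev$month, dev$latitude)
  dev$pft_group <- pft_group_of(dev$pft)
  agg_curve <- function(d) {
    per_member <- aggregate(absdev ~ scenario + n + month_aligned + member,
                            d, mean)
    out <- aggregate(absdev ~ scenario + n + month_aligned, per_member,
                     function(z) c(mean = mean(z), sd = sd(z)))
    data.frame(out[, c("scenario", "n", "month_aligned")],
               mad_mean = out$absdev[, "mean"], mad_sd = out$absdev[, "sd"])
  }
  curves <- do.call(rbind, lapply(split(dev, dev$pft_group), function(d)
    cbind(pft_group = d$pft_group[1], agg_curve(d))))
  curves_all <- cbind(pft_group = "all", agg_curve(dev))
  per_member_n <- aggregate(absdev ~ scenario + n + member, dev, mean)
  by_n <- aggregate(absdev ~ scenario + n, per_member_n,
                    function(z) c(mean = mean(z), sd = sd(z)))
  by_n <- data.frame(by_n[, c("scenario", "n")],
                     mad_mean = by_n$absdev[, "mean"],
                     mad_sd = by_n$absdev[, "sd"])
  list(curves = rbind(curves_all, curves), by_n = by_n, devs = dev,
       noise_floor = mean(floors))
}
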