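#' Build per-site sequence samples
#'
#' Converts the long panel into one sample per site: a T x 11 predictor
#' matrix (seven reflectance bands + tair, precip, rg, vpd, time-ordered
#' monthly), the NEE target with missingness, and the observation mask
#' (TRUE where NEE survives the window and quality filter). Predictor rows
#' must be complete, i.e. reflectance gap-filled beforehand or generated
#' without gaps.
#'
#' @param panels long panel data.frame.
#' @param sites site table.
#' @return list of samples, each
#'   `list(site_id, X, y, mask, year, month, latitude, pft)`.
#' @export
build_samples <- function(panels, sites) {
  lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    p <- panels[panels$site_id == s$site_id, ]
    p <- p[order(p$year, p$month), ]
    X <- as.matrix(p[, PREDICTORS])
    if (anyNA(X))
      stop("incomplete predictor rows for site ", s$site_id,
           "; gap-fill reflectance first")
    list(site_id = s$site_id, X = X, y = p$nee, mask = !is.na(p$nee),
         year = p$year, month = p$month, latitude = s$latitude, pft = s$pft)
  })
}

#' Predictor/target standardizer
#'
#' Fits per-predictor means and standard deviations over all months of the
#' supplied (training) sites, and the target mean/sd over observed months
#' only. Fitting on training folds only (never on test sites) is part of
#' the cross-validation contract and is asserted by the tests.
#'
#' @param samples list of sequence samples (training sites only).
#' @return an `fm_standardizer`.
#' @export
fit_standardizer <- function(samples) {
  X <- do.call(rbind, lapply(samples, `[[`, "X"))
  y <- unlist(lapply(samples, function(s) s$y[s$mask]))
  std <- list(x_mean = colMeans(X), x_sd = pmax(apply(X, 2, sd), 1e-8),
              y_mean = mean(y), y_sd = max(sd(y), 1e-8))
  class(std) <- "fm_standardizer"
  std
}

#' @rdname fit_standardizer
#' @param std a fitted standardizer.
#' @export
apply_standardizer <- function(samples, std) {
  lapply(samples, function(s) {
    s$X <- sweep(sweep(s$X, 2, std$x_mean), 2, std$x_sd, "/")
    s$y <- (s$y - std$y_mean) / std$y_sd
    s
  })
}

#' @rdname fit_standardizer
#' @param pred predictions on the standardized scale.
#' @export
invert_target <- function(std, pred) pred * std$y_sd + std$y_mean

# stack samples into the shapes the C++ kernel expects
samples_to_batch <- function(samples) {
  T_ <- nrow(samples[[1]]$X)
  stopifnot(all(vapply(samples, function(s) nrow(s$X), 0L) == T_))
  D <- ncol(samples[[1]]$X)
  S <- length(samples)
  X <- array(0, dim = c(T_, D, S))
  y <- matrix(0, T_, S)
  mask <- matrix(0L, T_, S)
  for (s in seq_len(S)) {
    X[, , s] <- samples[[s]]$X
    ys <- samples[[s]]$y
    ys[is.na(ys)] <- 0
    y[, s] <- ys
    mask[, s] <- as.integer(samples[[s]]$mask)
  }
  list(X = X, y = y, mask = mask)
}
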