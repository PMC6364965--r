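#' Static random-forest baseline
#'
#' The non-dynamic reference model: a tree-ensemble regression on the 11
#' instantaneous predictors, trained on observed months only and predicting
#' month-by-month with no temporal features. A single-row training set
#' degenerates to a constant predictor.
#'
#' @param X matrix/data.frame of instantaneous predictor rows (observed
#'   months only).
#' @param y NEE at those months.
#' @param seed integer seed.
#' @param num.trees forest size.
#' @return an `fm_static` model.
#' @export
train_static_baseline <- function(X, y, seed, num.trees = 200) {
  X <- as.data.frame(X)
  if (nrow(X) == 0 || length(y) == 0) stop("empty training rows")
  if (nrow(X) == 1)
    return(structure(list(type = "constant", value = y[1]),
                     class = "fm_static"))
  # canonical row order: the fit is invariant to how callers arrange rows
  ord <- do.call(order, c(unname(as.list(X)), list(y)))
  fit <- rf_fit(X[ord, , drop = FALSE], y[ord], seed = seed,
                num.trees = num.trees)
  structure(list(type = "ranger", fit = fit), class = "fm_static")
}

#' @rdname train_static_baseline
#' @param object an `fm_static` model.
#' @param newdata predictor rows to score.
#' @param ... unused.
#' @export
predict.fm_static <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (object$type == "constant") return(rep(object$value, nrow(newdata)))
  rf_predict(object$fit, newdata)
}

# pool observed (x_t, y_t) rows across a sample list
static_rows <- function(samples) {
  X <- do.call(rbind, lapply(samples, function(s) s$X[s$mask, , drop = FALSE]))
  y <- unlist(lapply(samples, function(s) s$y[s$mask]))
  list(X = X, y = y)
}
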