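#' Ordinary least-squares fit of a label on a single feature
#'
#' Fits `label = m * x + q` by closed-form OLS.  The coefficient of
#' determination is `1 - SSres/SStot` and the RMSE is `sqrt(SSres/n)`.
#' A zero-variance label yields `r2 = 0` with a warning (the convention used
#' throughout the formula search); a zero-variance feature yields the
#' constant fit `m = 0`, `q = mean(label)`.
#'
#' @param x numeric feature values.
#' @param y numeric labels (same length).
#' @param min_n minimum number of valid samples (default 3).
#' @param warn_zero_var warn when the label has zero variance (silenced for
#'   internal refits on small folds).
#' @return a list of class `fit_result`: `m`, `q`, `r2`, `rmse`,
#'   `predictions`, `n`, `excluded` (indices dropped as NA).
#' @export
fit_linear <- function(x, y, min_n = 3L, warn_zero_var = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  excluded <- which(!ok)
  x2 <- x[ok]; y2 <- y[ok]
  n <- length(x2)
  if (n < min_n) stop("fit_linear needs at least ", min_n, " valid samples, got ", n)
  mx <- mean(x2); my <- mean(y2)
  sxx <- sum((x2 - mx)^2); sxy <- sum((x2 - mx) * (y2 - my))
  if (sxx <= 0) { m <- 0; q <- my } else { m <- sxy / sxx; q <- my - m * mx }
  pred <- m * x2 + q
  ssres <- sum((y2 - pred)^2)
  sstot <- sum((y2 - my)^2)
  if (sstot <= 0) {
    if (warn_zero_var) warning("zero label variance; r2 defined as 0")
    r2 <- 0
  } else r2 <- 1 - ssres / sstot
  predictions <- rep(NA_real_, length(x))
  predictions[ok] <- pred
  structure(list(m = m, q = q, r2 = r2, rmse = sqrt(ssres / n),
                 predictions = predictions, n = n, excluded = excluded),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> m = %.5g, q = %.5g, r2 = %.4f, rmse = %.4f (n = %d)\n",
              x$m, x$q, x$r2, x$rmse, x$n))
  if (!is.null(x$loocv_rmse))
    cat(sprintf("  loocv_rmse = %.4f\n", x$loocv_rmse))
  invisible(x)
}

#' Leave-one-out cross-validation of a scoring function
#'
#' Holds out each sample in turn, refits the slope and intercept on the
#' remaining samples (the formula structure and per-term weights stay
#' fixed), predicts the held-out sample, and reports the RMSE over the
#' held-out predictions.  Samples where the feature is invalid (degenerate
#' denominator or domain violation) are excluded and reported.
#'
#' @param sf a [scoring_function()].
#' @param table feature table containing the BP columns and the label.
#' @param label name of the label column (default `"dG_exp"`).
#' @param refit_weights if `TRUE`, the per-term weight grid search is also
#'   re-run inside every fold (the stricter protocol).
#' @param grid_step weight-grid step used when `refit_weights = TRUE`.
#' @return a list: `loocv_rmse`, `predictions` (NA where excluded),
#'   `excluded` indices.
#' @export
loocv <- function(sf, table, label = "dG_exp", refit_weights = FALSE,
                  grid_step = 0.1) {
  stopifnot(inherits(sf, "scoring_function"))
  y <- table[[label]]
  if (is.null(y)) stop("label column '", label, "' not found")
  ev <- evaluate_feature(sf$feature, table, sf$weights)
  ok <- !ev$invalid & is.finite(y)
  idx <- which(ok)
  if (length(idx) < 3L) stop("LOOCV needs at least 3 valid samples")
  preds <- rep(NA_real_, length(y))
  for (i in idx) {
    train <- setdiff(idx, i)
    if (refit_weights) {
      sfi <- optimize_weights(sf$feature, table[train, , drop = FALSE],
                              label = label, step = grid_step)
      evi <- evaluate_feature(sf$feature, table, sfi$weights)
      f <- fit_linear(evi$values[train], y[train], min_n = 2L, warn_zero_var = FALSE)
      preds[i] <- f$m * evi$values[i] + f$q
    } else {
      f <- fit_linear(ev$values[train], y[train], min_n = 2L, warn_zero_var = FALSE)
      preds[i] <- f$m * ev$values[i] + f$q
    }
  }
  list(loocv_rmse = sqrt(mean((preds[idx] - y[idx])^2)),
       predictions = preds, excluded = which(!ok))
}

#' Correlation metrics between predictions and experimental labels
#'
#' Reports the coefficient of determination of the correlation line
#' (the squared Pearson correlation between predictions and labels, i.e.
#' the R2 of the least-squares line through the scatter plot) together with
#' the RMSE computed directly on `prediction - label`.
#'
#' @param predictions,labels numeric vectors of equal length.
#' @param exclude optional indices (or logical mask, or names) of samples to
#'   drop before computing the metrics.
#' @return a `fit_result` with `r2`, `rmse`, `n` and the fitted correlation
#'   line (`m`, `q`: label regressed on prediction).
#' @export
regression_metrics <- function(predictions, labels, exclude = NULL) {
  stopifnot(length(predictions) == length(labels))
  keep <- rep(TRUE, length(labels))
  if (!is.null(exclude)) {
    if (is.logical(exclude)) keep <- !exclude
    else if (is.character(exclude)) keep[names(labels) %in% exclude] <- FALSE
    else keep[exclude] <- FALSE
  }
  p <- predictions[keep]; y <- labels[keep]
  ok <- is.finite(p) & is.finite(y)
  p <- p[ok]; y <- y[ok]
  if (length(p) < 2L) stop("regression_metrics needs at least 2 samples")
  line <- fit_linear(p, y, min_n = 2L)
  line$rmse <- sqrt(mean((p - y)^2))
  line$n <- length(p)
  line
}
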