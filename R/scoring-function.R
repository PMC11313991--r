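#' Construct a scoring function
#'
#' A scoring function is a basic feature with per-term weights and a fitted
#' slope and intercept: `prediction = m * BF_w + q`, where `BF_w` is the
#' feature evaluated with weights (a, b) on the numerator terms and
#' (c[, d]) on the denominator terms.
#'
#' @param feature a [basic_feature()].
#' @param weights numeric vector of 3 (ratio3) or 4 (ratio4) weights.
#' @param m,q slope and intercept (kcal/mol when predicting binding free
#'   energies).
#' @param fit optional `fit_result` recording training metrics.
#' @param name optional label.
#' @return an object of class `scoring_function`.
#' @export
scoring_function <- function(feature, weights, m, q, fit = NULL, name = NULL) {
  stopifnot(inherits(feature, "basic_feature"))
  k <- if (feature$generator == "ratio4") 4L else 3L
  if (length(weights) != k) stop("expected ", k, " weights")
  structure(list(feature = feature, weights = as.numeric(weights),
                 m = as.numeric(m), q = as.numeric(q), fit = fit, name = name),
            class = "scoring_function")
}

#' @export
print.scoring_function <- function(x, ...) {
  cat("<scoring_function", if (!is.null(x$name)) paste0(" '", x$name, "'"), ">\n",
      "  ", format_formula(x$feature, x$weights, x$m, x$q), "\n", sep = "")
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' The published hCA II benzenesulfonamide scoring function
#'
#' The nonlinear scoring function discovered by the formula-generator search
#' on the nine-ligand hCA II descriptor set:
#' \deqn{\Delta G = -7.4 \frac{0.7\,\mathrm{logP}^3 - 0.5\,e^{\mathrm{HIE\text{-}E}}}
#'   {0.5\,\mathrm{F2LE}^3 - 0.4\,\mathrm{HIE\text{-}E}^5} - 13}
#' The coefficients are stored exactly as published and are never refit on
#' load.  The numerator combines the two hydrophobicity descriptors (logP
#' and the hydrophobic-interaction-energy efficiency); the denominator
#' balances the FMO ligand efficiency (polar/electrostatic binding) against
#' the hydrophobic efficiency.
#'
#' @return a [scoring_function()] over BP columns `logP`, `HIE_E`, `F2LE`.
#' @seealso [hca2_dataset()] for the matching descriptor table.
#' @export
hca2_scoring_function <- function() {
  bf <- basic_feature(
    num_f = c("x3", "exp"), num_bp = c("logP", "HIE_E"), num_op = "sub",
    den_f = c("x3", "x5"), den_bp = c("F2LE", "HIE_E"), den_op = "sub"
  )
  scoring_function(bf, weights = c(0.7, 0.5, 0.5, 0.4), m = -7.4, q = -13,
                   name = "hCA2-FMO/GRID")
}

#' Evaluate a scoring function on a feature table
#'
#' @param sf a [scoring_function()].
#' @param table data.frame with the required BP columns.
#' @return numeric vector of predictions (kcal/mol); `NA` with an
#'   `"errors"` attribute for samples with a degenerate denominator or
#'   domain violation.
#' @export
evaluate_scoring_function <- function(sf, table) {
  stopifnot(inherits(sf, "scoring_function"))
  ev <- evaluate_feature(sf$feature, table, sf$weights)
  pred <- sf$m * ev$values + sf$q
  if (any(ev$invalid)) {
    attr(pred, "errors") <- data.frame(
      sample = which(ev$invalid),
      reason = "degenerate denominator or domain violation"
    )
  }
  pred
}

#' Multilinear regression baseline
#'
#' Ordinary multilinear least squares of the label on a set of BP columns,
#' the classical way empirical scoring functions are calibrated.  Collinear
#' features trigger a rank-deficiency warning (the dropped coefficients are
#' reported as `NA`, as [stats::lm()] does).
#'
#' @param table feature table.
#' @param features character vector of BP column names.
#' @param label label column name (default `"dG_exp"`).
#' @param subset optional sample ids (matched against `table$ligand` if
#'   present, else row indices) to restrict the fit to.
#' @return a `fit_result` with an extra `coefficients` element
#'   (intercept first).
#' @export
multilinear_baseline <- function(table, features, label = "dG_exp", subset = NULL) {
  missing_f <- setdiff(c(features, label), names(table))
  if (length(missing_f)) stop("missing column(s): ", paste(missing_f, collapse = ", "))
  if (!is.null(subset)) {
    rows <- if ("ligand" %in% names(table)) match(subset, table$ligand) else subset
    if (anyNA(rows)) stop("unknown sample id(s) in subset")
    table <- table[rows, , drop = FALSE]
  }
  y <- table[[label]]
  if (!all(is.finite(y))) stop("label contains non-finite values")
  n <- nrow(table)
  if (n <= length(features)) stop("need more samples than features")
  d <- table[, features, drop = FALSE]
  d[[".y"]] <- y
  fit <- stats::lm(.y ~ ., data = d)
  if (anyNA(stats::coef(fit)))
    warning("collinear features: rank-deficient fit, some coefficients NA")
  pred <- stats::fitted(fit)
  ssres <- sum(stats::resid(fit)^2)
  sstot <- sum((y - mean(y))^2)
  out <- structure(list(
    m = NA_real_, q = unname(stats::coef(fit)[1]),
    r2 = if (sstot > 0) 1 - ssres / sstot else 0,
    rmse = sqrt(ssres / n),
    predictions = unname(pred), n = n, excluded = integer(0),
    coefficients = stats::coef(fit)
  ), class = "fit_result")
  out
}

#' Convert an inhibition constant to an experimental binding free energy
#'
#' \deqn{\Delta G_{exp} = RT \ln K_i}
#' with the gas constant R = 1.9872e-3 kcal/(mol K).
#'
#' @param ki inhibition constant in molar units (> 0).
#' @param temperature absolute temperature in kelvin (default 298.15).
#' @return binding free energy in kcal/mol (negative for sub-molar Ki).
#' @export
delta_g_from_ki <- function(ki, temperature = 298.15) {
  if (any(!is.finite(ki)) || any(ki <= 0)) stop("ki must be positive and finite")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive")
  R_KCAL <- 1.9872e-3
  R_KCAL * temperature * log(ki)
}
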