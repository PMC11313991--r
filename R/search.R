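#' Grid-search optimization of per-term weights
#'
#' Exhaustively scans all weight tuples on the grid `{0, step, ..., 1}` for
#' the 3 (ratio3) or 4 (ratio4) terms of a basic feature.  For every tuple
#' the weighted feature is re-evaluated and the slope and intercept are
#' refit by OLS; the tuple with the highest R2 wins, ties broken in favour
#' of the lexicographically largest tuple.  Tuples whose weighted numerator
#' or denominator is identically zero, or that make any training sample
#' invalid, are skipped as degenerate.
#'
#' Note the scale degeneracy: multiplying both numerator weights by a
#' constant divides the fitted slope by the same constant and leaves
#' predictions unchanged, so maximal-R2 tuples come in equivalence classes.
#'
#' @param bf a [basic_feature()].
#' @param table feature table with BP columns and the label.
#' @param label label column name (default `"dG_exp"`).
#' @param step grid step; must divide 1 exactly (default 0.1, i.e. 11
#'   values per weight).
#' @param tol denominator-degeneracy tolerance.
#' @return a [scoring_function()] whose `fit` records the training metrics.
#' @export
optimize_weights <- function(bf, table, label = "dG_exp", step = 0.1, tol = 1e-9) {
  stopifnot(inherits(bf, "basic_feature"))
  nsteps <- 1 / step
  if (abs(nsteps - round(nsteps)) > 1e-8) stop("step must divide 1.0")
  vals <- seq(0, 1, by = step)
  y <- table[[label]]
  if (is.null(y)) stop("label column '", label, "' not found")
  ok_y <- is.finite(y)
  if (sum(ok_y) < 3L) stop("need at least 3 labelled samples")
  tab <- table[ok_y, , drop = FALSE]
  y <- y[ok_y]
  n <- length(y)

  k <- if (bf$generator == "ratio4") 4L else 3L
  t1 <- apply_prototype(bf$num$f[1], tab[[bf$num$bp[1]]])
  t2 <- apply_prototype(bf$num$f[2], tab[[bf$num$bp[2]]])
  d1 <- apply_prototype(bf$den$f[1], tab[[bf$den$bp[1]]])
  d2 <- if (k == 4L) apply_prototype(bf$den$f[2], tab[[bf$den$bp[2]]]) else NULL

  ## lexicographic ascending order in (a, b, c, d): last weight fastest
  grid <- if (k == 4L)
    expand.grid(d = vals, c = vals, b = vals, a = vals)[, c("a", "b", "c", "d")]
  else
    expand.grid(c = vals, b = vals, a = vals)[, c("a", "b", "c")]

  NUM <- apply_op(bf$num$op, outer(grid$a, t1), outer(grid$b, t2))
  DEN <- outer(grid$c, d1)
  if (k == 4L) DEN <- apply_op(bf$den$op, DEN, outer(grid$d, d2))
  bad_entry <- !is.finite(NUM) | !is.finite(DEN) | abs(DEN) < tol
  degenerate <- apply(abs(NUM), 1, max) < tol | apply(abs(DEN), 1, max) < tol |
    rowSums(bad_entry) > 0
  FVAL <- NUM / DEN

  my <- mean(y); yc <- y - my
  syy <- sum(yc^2)
  rm_ <- rowMeans(FVAL)
  Fc <- FVAL - rm_
  sxx <- rowSums(Fc^2)
  sxy <- as.vector(Fc %*% yc)
  r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), 0)
  r2[degenerate] <- -Inf
  if (all(!is.finite(r2)))
    stop("weight optimization failed: every tuple is degenerate on this table")
  best_r2 <- max(r2)
  best <- max(which(r2 >= best_r2 - 1e-10))
  w <- as.numeric(grid[best, ])
  ev <- evaluate_feature(bf, tab, w, tol = tol)
  fit <- fit_linear(ev$values, y)
  scoring_function(bf, w, fit$m, fit$q, fit = fit)
}

#' Run the full formula-generator search
#'
#' The complete discovery pipeline: enumerate every basic feature for the
#' declared basic properties, evaluate each on the table, rank by the R2 of
#' a single-feature OLS fit to the label, carry the top `top_n` formulas of
#' each generator into the exhaustive weight grid search, and cross-validate
#' the optimized scoring functions by LOOCV.  Features with any invalid
#' training sample (degenerate denominator, domain violation, non-finite
#' value) are discarded.  The procedure is fully deterministic: identical
#' inputs give identical ranked output (ties in the ranking are broken by
#' enumeration order).
#'
#' @param table feature table: one row per sample, BP columns plus label.
#' @param bps a [basic_properties()] declaration for the columns to use.
#' @param label label column name (default `"dG_exp"`).
#' @param generators subset of `c("ratio3", "ratio4")`.
#' @param top_n formulas per generator carried to weight optimization
#'   (default 10).
#' @param grid_step weight-grid step (default 0.1).
#' @param tol denominator-degeneracy tolerance.
#' @param relax_positivity see [enumerate_basic_features()].
#' @param run_loocv compute LOOCV RMSE for each optimized formula
#'   (default `TRUE`).
#' @param chunk_size features evaluated per block during ranking.
#' @return an object of class `fg_search`: `results` (list of per-formula
#'   records, best first), `summary` (data.frame), `diagnostics`.
#' @export
run_search <- function(table, bps, label = "dG_exp",
                       generators = c("ratio3", "ratio4"), top_n = 10,
                       grid_step = 0.1, tol = 1e-9, relax_positivity = FALSE,
                       run_loocv = TRUE, chunk_size = 50000L) {
  bps <- as_bp_info(bps)
  y <- table[[label]]
  if (is.null(y)) stop("label column '", label, "' not found")
  ok_y <- is.finite(y)
  tab <- table[ok_y, , drop = FALSE]
  y <- y[ok_y]
  n <- length(y)
  if (n < 3L) stop("need at least 3 labelled samples")

  set <- enumerate_basic_features(bps, generators, relax_positivity)
  diagnostics <- list(n_features = nrow(set), n_valid = 0L, n_samples = n)
  if (nrow(set) == 0L)
    return(structure(list(results = list(), summary = empty_search_summary(),
                          diagnostics = diagnostics), class = "fg_search"))

  ## cache prototype-transformed BP columns once
  term_key <- function(f, bp) paste(f, bp, sep = "\r")
  keys <- unique(c(term_key(set$nf1, set$nbp1), term_key(set$nf2, set$nbp2),
                   term_key(set$df1, set$dbp1),
                   term_key(set$df2[!is.na(set$df2)], set$dbp2[!is.na(set$df2)])))
  V <- vapply(keys, function(k) {
    p <- strsplit(k, "\r", fixed = TRUE)[[1]]
    apply_prototype(p[1], tab[[p[2]]])
  }, numeric(n))
  if (n == 1L) V <- matrix(V, nrow = 1, dimnames = list(NULL, keys))
  i1 <- match(term_key(set$nf1, set$nbp1), keys)
  i2 <- match(term_key(set$nf2, set$nbp2), keys)
  i3 <- match(term_key(set$df1, set$dbp1), keys)
  i4 <- ifelse(is.na(set$df2), NA_integer_, match(term_key(set$df2, set$dbp2), keys))

  my <- mean(y); yc <- y - my; syy <- sum(yc^2)
  nf <- nrow(set)
  r2_all <- numeric(nf)
  valid_all <- logical(nf)
  for (start in seq(1L, nf, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, nf)
    NUM <- matrix(NA_real_, n, length(idx))
    DEN <- matrix(NA_real_, n, length(idx))
    for (op in OP_KINDS) {
      sel <- which(set$nop[idx] == op)
      if (length(sel))
        NUM[, sel] <- apply_op(op, V[, i1[idx[sel]], drop = FALSE],
                               V[, i2[idx[sel]], drop = FALSE])
    }
    r3 <- which(is.na(i4[idx]))
    if (length(r3)) DEN[, r3] <- V[, i3[idx[r3]], drop = FALSE]
    for (op in OP_KINDS) {
      sel <- which(!is.na(i4[idx]) & set$dop[idx] == op)
      if (length(sel))
        DEN[, sel] <- apply_op(op, V[, i3[idx[sel]], drop = FALSE],
                               V[, i4[idx[sel]], drop = FALSE])
    }
    FV <- NUM / DEN
    bad <- !is.finite(FV) | abs(DEN) < tol
    valid <- colSums(bad) == 0L
    FV[bad] <- 0
    fm <- colMeans(FV)
    Fc <- FV - rep(fm, each = n)
    sxx <- colSums(Fc^2)
    sxy <- as.vector(crossprod(Fc, yc))
    r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), 0)
    r2[!valid] <- -Inf
    r2_all[idx] <- r2
    valid_all[idx] <- valid
  }
  diagnostics$n_valid <- sum(valid_all)
  if (diagnostics$n_valid == 0L)
    return(structure(list(results = list(), summary = empty_search_summary(),
                          diagnostics = diagnostics), class = "fg_search"))

  picked <- unlist(lapply(unique(set$gen), function(g) {
    cand <- which(set$gen == g & valid_all)
    cand[order(-r2_all[cand], cand)][seq_len(min(top_n, length(cand)))]
  }), use.names = FALSE)

  results <- lapply(picked, function(i) {
    bf <- bf_from_set(set, i)
    sf <- optimize_weights(bf, tab, label = label, step = grid_step, tol = tol)
    cv <- if (run_loocv) loocv(sf, tab, label = label) else NULL
    list(feature = bf, sf = sf, generator = set$gen[i],
         r2_unweighted = r2_all[i], r2 = sf$fit$r2, rmse = sf$fit$rmse,
         loocv_rmse = if (is.null(cv)) NA_real_ else cv$loocv_rmse,
         n_samples = n, enum_index = i)
  })
  ord <- order(-vapply(results, `[[`, 0, "r2"),
               vapply(results, `[[`, 0L, "enum_index"))
  results <- results[ord]

  summary <- do.call(rbind, lapply(seq_along(results), function(r) {
    x <- results[[r]]
    data.frame(rank = r, generator = x$generator,
               formula = format_formula(x$feature, x$sf$weights, x$sf$m, x$sf$q),
               weights = paste(formatC(x$sf$weights, format = "g"), collapse = ","),
               m = x$sf$m, q = x$sf$q, r2 = x$r2, r2_unweighted = x$r2_unweighted,
               rmse = x$rmse, loocv_rmse = x$loocv_rmse, n_samples = x$n_samples,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, summary = summary, diagnostics = diagnostics),
            class = "fg_search")
}

empty_search_summary <- function() {
  data.frame(rank = integer(0), generator = character(0), formula = character(0),
             weights = character(0), m = numeric(0), q = numeric(0),
             r2 = numeric(0), r2_unweighted = numeric(0), rmse = numeric(0),
             loocv_rmse = numeric(0), n_samples = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.fg_search <- function(x, ...) {
  cat(sprintf("<fg_search> %d features enumerated, %d valid, %d optimized\n",
              x$diagnostics$n_features, x$diagnostics$n_valid,
              length(x$results)))
  if (nrow(x$summary))
    print(utils::head(x$summary[, c("rank", "generator", "r2", "rmse",
                                    "loocv_rmse", "formula")], 5))
  invisible(x)
}

#' Serialize ranked scoring functions to JSON formula records
#'
#' @param search an `fg_search` result.
#' @param path output file; if `NULL` the JSON string is returned.
#' @return (invisibly) the JSON string.
#' @export
write_formula_json <- function(search, path = NULL) {
  stopifnot(inherits(search, "fg_search"))
  recs <- lapply(search$results, function(x) {
    list(generator = x$generator,
         terms = list(numerator = list(f = x$feature$num$f, bp = x$feature$num$bp,
                                       op = x$feature$num$op),
                      denominator = list(f = x$feature$den$f, bp = x$feature$den$bp,
                                         op = x$feature$den$op)),
         weights = x$sf$weights, m = x$sf$m, q = x$sf$q,
         r2 = x$r2, rmse = x$rmse, loocv_rmse = x$loocv_rmse,
         n_samples = x$n_samples,
         formula = format_formula(x$feature, x$sf$weights, x$sf$m, x$sf$q))
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
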