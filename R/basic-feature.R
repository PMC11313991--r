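#' Declare a set of basic properties
#'
#' Basic properties (BPs) are the raw per-sample descriptors the formula
#' generator combines: FMO energy terms, hydrophobic interaction energies,
#' logP, or any other numeric feature.  Each BP carries a positivity flag
#' (gating even powers and the square root) and an optional exclusivity
#' group: at most one BP from a group may appear in a single formula,
#' which is how alternative representations of the same physical quantity
#' (e.g. the four FMO binding-strength estimates) are kept from being mixed.
#'
#' @param name character vector of BP names (must match feature-table columns).
#' @param positive_definite logical vector (recycled); `TRUE` if the BP is
#'   strictly positive over its domain.
#' @param group optional character vector of exclusivity-group labels
#'   (`NA` = no group).
#' @return a `data.frame` of class `bp_info`.
#' @export
basic_properties <- function(name, positive_definite = FALSE, group = NA_character_) {
  stopifnot(is.character(name), length(name) > 0, !anyDuplicated(name))
  out <- data.frame(
    name = name,
    positive_definite = rep_len(as.logical(positive_definite), length(name)),
    group = rep_len(as.character(group), length(name)),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$positive_definite))
    stop("positive_definite flags must be TRUE/FALSE, not NA")
  class(out) <- c("bp_info", "data.frame")
  out
}

as_bp_info <- function(bps) {
  if (inherits(bps, "bp_info")) return(bps)
  if (is.character(bps)) return(basic_properties(bps))
  if (is.data.frame(bps)) {
    if (!"name" %in% names(bps)) stop("bp_info data.frame needs a 'name' column")
    return(basic_properties(
      bps$name,
      if ("positive_definite" %in% names(bps)) bps$positive_definite else FALSE,
      if ("group" %in% names(bps)) bps$group else NA_character_
    ))
  }
  stop("cannot interpret basic-property declaration of class ",
       paste(class(bps), collapse = "/"))
}

#' Construct a basic feature
#'
#' A basic feature (BF) is a rational combination of prototype-transformed
#' BPs produced by one of two generators: a two-term numerator over a
#' single-term denominator (`ratio3`), or a two-term numerator over a
#' two-term denominator (`ratio4`).  Numerator terms always use two distinct
#' BPs; a ratio4 feature uses three or four distinct BPs in total (one BP
#' may be shared between numerator and denominator).
#'
#' @param num_f,num_bp length-2 character vectors: prototype function and BP
#'   name of the two numerator terms.
#' @param num_op `"add"`, `"sub"` or `"mul"`.
#' @param den_f,den_bp length-1 (ratio3) or length-2 (ratio4) vectors for the
#'   denominator.
#' @param den_op operator for a two-term denominator (`NA` for ratio3).
#' @return an object of class `basic_feature`.
#' @export
basic_feature <- function(num_f, num_bp, num_op, den_f, den_bp, den_op = NA_character_) {
  stopifnot(length(num_f) == 2, length(num_bp) == 2,
            length(den_f) %in% 1:2, length(den_f) == length(den_bp))
  num_op <- match.arg(num_op, OP_KINDS)
  generator <- if (length(den_f) == 1L) "ratio3" else "ratio4"
  if (generator == "ratio4") den_op <- match.arg(den_op, OP_KINDS)
  num_f <- vapply(num_f, match.arg, "", choices = PROTO_FUNS)
  den_f <- vapply(den_f, match.arg, "", choices = PROTO_FUNS)
  if (num_bp[1] == num_bp[2]) stop("numerator must use two distinct BPs")
  if (generator == "ratio4" && den_bp[1] == den_bp[2])
    stop("ratio4 denominator must use two distinct BPs")
  n_distinct <- length(unique(c(num_bp, den_bp)))
  if (generator == "ratio3" && n_distinct != 3L)
    stop("ratio3 features use exactly 3 distinct BPs")
  if (generator == "ratio4" && !n_distinct %in% 3:4)
    stop("ratio4 features use 3 or 4 distinct BPs")
  structure(
    list(generator = generator,
         num = list(f = unname(num_f), bp = unname(num_bp), op = num_op),
         den = list(f = unname(den_f), bp = unname(den_bp),
                    op = if (generator == "ratio4") den_op else NA_character_)),
    class = "basic_feature"
  )
}

#' Human-readable formula string for a basic feature
#'
#' @param bf a `basic_feature`.
#' @param weights optional numeric weights (a, b, c and, for ratio4, d).
#' @param m,q optional fitted slope and intercept.
#' @return a single string such as
#'   `"[(logP)^3 - e^(HIE_E)] / [(F2LE)^3 - (HIE_E)^5]"`.
#' @export
format_formula <- function(bf, weights = NULL, m = NULL, q = NULL) {
  stopifnot(inherits(bf, "basic_feature"))
  k <- if (bf$generator == "ratio4") 4L else 3L
  w <- if (is.null(weights)) rep(NA_real_, 4) else c(weights, NA_real_)[1:4]
  num <- paste(proto_label(bf$num$f[1], bf$num$bp[1], w[1]),
               OP_SYMBOLS[[bf$num$op]],
               proto_label(bf$num$f[2], bf$num$bp[2], w[2]))
  den <- proto_label(bf$den$f[1], bf$den$bp[1], w[3])
  if (bf$generator == "ratio4")
    den <- paste(den, OP_SYMBOLS[[bf$den$op]],
                 proto_label(bf$den$f[2], bf$den$bp[2], w[4]))
  s <- sprintf("[%s] / [%s]", num, den)
  if (!is.null(m)) s <- sprintf("%.6g * {%s} + %.6g", m, s,
                                if (is.null(q)) 0 else q)
  s
}

#' @export
print.basic_feature <- function(x, ...) {
  cat("<basic_feature ", x$generator, "> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Enumerate all basic features for a set of basic properties
#'
#' Exhaustively generates the duplicate-free list of basic features under
#' the combinatorial conventions:
#' \itemize{
#'   \item each BP is transformed by its allowed prototype functions only
#'     (even powers and square root require positive-definite BPs);
#'   \item numerator (and ratio4 denominator) pairs of (function, BP) terms
#'     are unordered for `+` and `*` and ordered for `-`;
#'   \item the two terms of a pair use distinct BPs; ratio3 uses three
#'     distinct BPs, ratio4 uses three or four;
#'   \item at most one BP per exclusivity group appears in a feature.
#' }
#'
#' @param bps a [basic_properties()] declaration (or character vector of names).
#' @param generators subset of `c("ratio3", "ratio4")`.
#' @param relax_positivity allow even powers on sign-indefinite BPs.
#' @return a `data.frame` of class `bf_set`, one row per feature, with
#'   columns `gen`, `nf1`, `nbp1`, `nop`, `nf2`, `nbp2`, `df1`, `dbp1`,
#'   `dop`, `df2`, `dbp2` (the last three `NA` for ratio3).
#' @export
enumerate_basic_features <- function(bps, generators = c("ratio3", "ratio4"),
                                     relax_positivity = FALSE) {
  bps <- as_bp_info(bps)
  generators <- match.arg(generators, several.ok = TRUE)
  empty <- bf_set(NULL)
  if (nrow(bps) < 3L) return(empty)

  ## term catalog: one row per (prototype function, BP)
  items <- do.call(rbind, lapply(seq_len(nrow(bps)), function(i) {
    funs <- allowed_prototypes(bps$positive_definite[i], relax_positivity)
    data.frame(f = funs, bp = bps$name[i], bpi = i,
               grp = bps$group[i], stringsAsFactors = FALSE)
  }))
  K <- nrow(items)

  pair_idx <- function() {
    ## unordered pairs (i < j) and ordered pairs, both restricted to
    ## distinct BPs and compatible exclusivity groups
    g <- expand.grid(i = seq_len(K), j = seq_len(K))
    g <- g[items$bpi[g$i] != items$bpi[g$j], , drop = FALSE]
    ok_grp <- is.na(items$grp[g$i]) | is.na(items$grp[g$j]) |
      items$grp[g$i] != items$grp[g$j]
    g <- g[ok_grp, , drop = FALSE]
    list(unordered = g[g$i < g$j, , drop = FALSE], ordered = g)
  }
  px <- pair_idx()
  pairs_for_op <- function(op) if (op == "sub") px$ordered else px$unordered

  ## pair table: i, j, op
  pairs <- do.call(rbind, lapply(OP_KINDS, function(op) {
    p <- pairs_for_op(op)
    if (nrow(p) == 0) return(NULL)
    data.frame(i = p$i, j = p$j, op = op, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)

  out <- list()
  if ("ratio3" %in% generators) {
    ## denominator: any single term whose BP differs from both numerator BPs
    ## (ratio3 requires 3 distinct BPs) and respects exclusivity
    grid <- expand.grid(p = seq_len(nrow(pairs)), d = seq_len(K))
    pi1 <- items$bpi[pairs$i[grid$p]]; pi2 <- items$bpi[pairs$j[grid$p]]
    di <- items$bpi[grid$d]
    keep <- di != pi1 & di != pi2
    gd <- items$grp[grid$d]
    g1 <- items$grp[pairs$i[grid$p]]; g2 <- items$grp[pairs$j[grid$p]]
    keep <- keep & (is.na(gd) | ((is.na(g1) | gd != g1) & (is.na(g2) | gd != g2)))
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid) > 0) {
      p <- pairs[grid$p, ]; d <- grid$d
      out$ratio3 <- data.frame(
        gen = "ratio3",
        nf1 = items$f[p$i], nbp1 = items$bp[p$i], nop = p$op,
        nf2 = items$f[p$j], nbp2 = items$bp[p$j],
        df1 = items$f[d], dbp1 = items$bp[d],
        dop = NA_character_, df2 = NA_character_, dbp2 = NA_character_,
        stringsAsFactors = FALSE
      )
    }
  }
  if ("ratio4" %in% generators) {
    grid <- expand.grid(p = seq_len(nrow(pairs)), q = seq_len(nrow(pairs)))
    np <- pairs[grid$p, ]; dp <- pairs[grid$q, ]
    b <- cbind(items$bpi[np$i], items$bpi[np$j], items$bpi[dp$i], items$bpi[dp$j])
    ndist <- apply(b, 1, function(r) length(unique(r)))
    keep <- ndist >= 3L
    ## exclusivity across numerator/denominator (within-pair already enforced):
    ## any two *different* BPs sharing a group are forbidden
    gmat <- cbind(items$grp[np$i], items$grp[np$j], items$grp[dp$i], items$grp[dp$j])
    grp_ok <- vapply(seq_len(nrow(b)), function(r) {
      u <- !duplicated(b[r, ])
      g <- gmat[r, u]
      g <- g[!is.na(g)]
      !anyDuplicated(g)
    }, logical(1))
    keep <- keep & grp_ok
    np <- np[keep, , drop = FALSE]; dp <- dp[keep, , drop = FALSE]
    if (nrow(np) > 0) {
      out$ratio4 <- data.frame(
        gen = "ratio4",
        nf1 = items$f[np$i], nbp1 = items$bp[np$i], nop = np$op,
        nf2 = items$f[np$j], nbp2 = items$bp[np$j],
        df1 = items$f[dp$i], dbp1 = items$bp[dp$i],
        dop = dp$op, df2 = items$f[dp$j], dbp2 = items$bp[dp$j],
        stringsAsFactors = FALSE
      )
    }
  }
  bf_set(do.call(rbind, out))
}

bf_set <- function(df) {
  cols <- c("gen", "nf1", "nbp1", "nop", "nf2", "nbp2",
            "df1", "dbp1", "dop", "df2", "dbp2")
  if (is.null(df) || nrow(df) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("bf_set", "data.frame")
  df
}

#' Extract one basic feature from an enumeration table
#'
#' @param set a `bf_set` from [enumerate_basic_features()].
#' @param i row index.
#' @return a `basic_feature`.
#' @export
bf_from_set <- function(set, i) {
  r <- set[i, ]
  if (r$gen == "ratio3") {
    basic_feature(c(r$nf1, r$nf2), c(r$nbp1, r$nbp2), r$nop, r$df1, r$dbp1)
  } else {
    basic_feature(c(r$nf1, r$nf2), c(r$nbp1, r$nbp2), r$nop,
                  c(r$df1, r$df2), c(r$dbp1, r$dbp2), r$dop)
  }
}

#' Evaluate a basic feature on a feature table
#'
#' Computes the per-sample value of a (optionally weighted) basic feature.
#' A sample is flagged invalid when the denominator magnitude falls below
#' `tol`, when a prototype-function domain is violated (square root of a
#' negative value), or when any term is non-finite.
#'
#' @param bf a `basic_feature`.
#' @param table a data.frame containing all BP columns.
#' @param weights optional numeric vector (a, b, c[, d]) multiplying each
#'   prototype term; defaults to all 1.
#' @param tol denominator-degeneracy tolerance (default `1e-9`).
#' @return a list with `values` (numeric, `NA` where invalid), `invalid`
#'   (logical), `numerator` and `denominator` vectors.
#' @export
evaluate_feature <- function(bf, table, weights = NULL, tol = 1e-9) {
  stopifnot(inherits(bf, "basic_feature"), is.data.frame(table))
  need <- unique(c(bf$num$bp, bf$den$bp))
  missing_bp <- setdiff(need, names(table))
  if (length(missing_bp))
    stop("feature table lacks BP column(s): ", paste(missing_bp, collapse = ", "))
  k <- if (bf$generator == "ratio4") 4L else 3L
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k)
    stop("expected ", k, " weights for a ", bf$generator, " feature")

  t1 <- apply_prototype(bf$num$f[1], table[[bf$num$bp[1]]])
  t2 <- apply_prototype(bf$num$f[2], table[[bf$num$bp[2]]])
  num <- apply_op(bf$num$op, weights[1] * t1, weights[2] * t2)
  d1 <- apply_prototype(bf$den$f[1], table[[bf$den$bp[1]]])
  den <- weights[3] * d1
  if (bf$generator == "ratio4") {
    d2 <- apply_prototype(bf$den$f[2], table[[bf$den$bp[2]]])
    den <- apply_op(bf$den$op, den, weights[4] * d2)
  }
  invalid <- !is.finite(num) | !is.finite(den) | abs(den) < tol
  values <- num / den
  invalid <- invalid | !is.finite(values)
  values[invalid] <- NA_real_
  list(values = values, invalid = invalid, numerator = num, denominator = den)
}
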