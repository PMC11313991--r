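#' @keywords internal
"_PACKAGE"

## Prototype functions applicable to a basic property (BP).  Even powers and
## the square root are restricted to positive-definite BPs because they
## destroy sign information (x^2, x^4) or leave the real domain (sqrt).
PROTO_FUNS <- c("x", "x2", "x3", "x4", "x5", "exp", "sqrt")
PROTO_POSITIVE_ONLY <- c("x2", "x4", "sqrt")

PROTO_LABELS <- c(
  x = "%s", x2 = "(%s)^2", x3 = "(%s)^3", x4 = "(%s)^4", x5 = "(%s)^5",
  exp = "e^(%s)", sqrt = "sqrt(%s)"
)

OP_KINDS <- c("add", "sub", "mul")
OP_SYMBOLS <- c(add = "+", sub = "-", mul = "*")

#' Apply a prototype function to numeric values
#'
#' The seven prototype functions are the identity, integer powers 2--5, the
#' exponential and the square root.  The exponential argument is clamped at
#' |x| <= 50 to avoid overflow; the square root of a negative value is NaN
#' and flags the sample as invalid downstream.
#'
#' @param fun one of `"x"`, `"x2"`, `"x3"`, `"x4"`, `"x5"`, `"exp"`, `"sqrt"`.
#' @param v numeric vector.
#' @return numeric vector of the same length.
#' @export
apply_prototype <- function(fun, v) {
  fun <- match.arg(fun, PROTO_FUNS)
  switch(fun,
    x = v,
    x2 = v^2,
    x3 = v^3,
    x4 = v^4,
    x5 = v^5,
    exp = exp(pmin(pmax(v, -50), 50)),
    sqrt = suppressWarnings(sqrt(v))
  )
}

#' Allowed prototype functions for a basic property
#'
#' @param positive_definite logical; is the BP strictly positive on its whole
#'   range?
#' @param relax_positivity if `TRUE`, even powers (but not the square root)
#'   are allowed for sign-indefinite BPs.
#' @return character vector of prototype-function names.
#' @export
allowed_prototypes <- function(positive_definite, relax_positivity = FALSE) {
  if (isTRUE(positive_definite)) return(PROTO_FUNS)
  drop <- if (relax_positivity) "sqrt" else PROTO_POSITIVE_ONLY
  setdiff(PROTO_FUNS, drop)
}

apply_op <- function(op, a, b) {
  switch(op, add = a + b, sub = a - b, mul = a * b,
         stop("unknown operator: ", op))
}

proto_label <- function(fun, bp, weight = NULL) {
  term <- sprintf(PROTO_LABELS[[fun]], bp)
  if (is.null(weight) || is.na(weight)) term else sprintf("%.3g*%s", weight, term)
}
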