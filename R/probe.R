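#' Default DRY-probe parameters
#'
#' A generic, editable parameter set for the hydrophobic probe: per-element
#' 12-6 Lennard-Jones well depths and minimum distances (probe-atom
#' combined values), a radial hydrogen-bond term applied with inverted sign
#' to donor/acceptor elements (so polar contacts penalize the hydrophobic
#' score), and the constant hydration-entropy reward added at every grid
#' point.  These are deliberately generic values for a GRID-like evaluator,
#' not a proprietary force-field table; edit the returned list to retune.
#'
#' The entropy constant is stored as the literal -0.848 kcal/mol (RT ln 4
#' at the temperature implied by that figure) rather than recomputed from a
#' temperature argument.
#'
#' @param delta_s constant entropic term, kcal/mol (default -0.848).
#' @param lj_cutoff,hb_cutoff interaction cutoffs in angstrom; beyond
#'   `lj_cutoff` from every atom a point evaluates exactly to `delta_s`.
#' @param core_clamp maximum energy (kcal/mol) assigned to points inside an
#'   atomic core during field evaluation.
#' @return a list of class `probe_params` with elements `lj`
#'   (data.frame `element`, `eps`, `rmin`), `hbond`
#'   (data.frame `element`, `eps`, `r0`), `delta_s`, `lj_cutoff`,
#'   `hb_cutoff`, `core_clamp`.
#' @export
default_probe_params <- function(delta_s = -0.848, lj_cutoff = 8,
                                 hb_cutoff = 5, core_clamp = 5) {
  stopifnot(lj_cutoff > 0, hb_cutoff > 0)
  lj <- data.frame(
    element = c("C", "N", "O", "S", "P", "H", "F", "CL", "BR", "I", "ZN"),
    eps  = c(0.15, 0.16, 0.17, 0.20, 0.20, 0.02, 0.08, 0.26, 0.32, 0.40, 0.10),
    rmin = c(4.00, 3.75, 3.60, 4.00, 4.10, 2.80, 3.50, 3.90, 4.10, 4.30, 2.80),
    stringsAsFactors = FALSE
  )
  hbond <- data.frame(
    element = c("N", "O"),
    eps = c(2.0, 2.8),
    r0 = c(3.0, 2.8),
    stringsAsFactors = FALSE
  )
  structure(list(lj = lj, hbond = hbond, delta_s = delta_s,
                 lj_cutoff = lj_cutoff, hb_cutoff = hb_cutoff,
                 core_clamp = core_clamp),
            class = "probe_params")
}

## normalize any supported structure input to data.frame(elem, x, y, z)
as_atom_table <- function(structure) {
  if (inherits(structure, "complex_structure")) structure <- structure$atoms
  if (inherits(structure, "pdb")) structure <- structure$atom
  if (!is.data.frame(structure))
    stop("structure must be a data.frame of atoms, a bio3d pdb, ",
         "or a complex_structure")
  if (!"elem" %in% names(structure)) {
    if ("elesy" %in% names(structure)) structure$elem <- structure$elesy
    else stop("atom table needs an 'elem' column")
  }
  need <- c("elem", "x", "y", "z")
  if (!all(need %in% names(structure)))
    stop("atom table needs columns: ", paste(need, collapse = ", "))
  structure$elem <- toupper(trimws(structure$elem))
  structure
}

#' Build an axis-aligned grid around a structure
#'
#' The grid covers the structure's bounding box extended by `margin` on all
#' sides, with points every `spacing` angstrom (the point count per axis is
#' rounded up so the box is always enclosed).
#'
#' @param structure atoms (see [as_atom_table()] inputs).
#' @param spacing grid spacing in angstrom (> 0, default 0.5).
#' @param margin box extension in angstrom (> 0, default 4).
#' @return an object of class `grid_spec`: `origin` (length-3), `spacing`,
#'   `dim` (nx, ny, nz).
#' @export
build_grid <- function(structure, spacing = 0.5, margin = 4) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (!is.finite(margin) || margin < 0) stop("margin must be >= 0")
  at <- as_atom_table(structure)
  if (nrow(at) == 0) stop("empty structure")
  lo <- c(min(at$x), min(at$y), min(at$z)) - margin
  hi <- c(max(at$x), max(at$y), max(at$z)) + margin
  dim <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)) + 1L)
  out <- list(origin = lo, spacing = spacing, dim = dim)
  class(out) <- "grid_spec"
  out
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d points, spacing %.3g A, origin (%.2f, %.2f, %.2f)\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid point coordinates
#'
#' @param grid a `grid_spec`.
#' @return matrix (n points x 3), x fastest-varying.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ax <- lapply(1:3, function(k) grid$origin[k] + grid$spacing * (seq_len(grid$dim[k]) - 1))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

## DRY probe energy for a matrix of points; vectorized core used by both
## dry_point_energy and compute_field
dry_energy_points <- function(pts, at, params) {
  n <- nrow(pts)
  e <- rep(params$delta_s, n)
  lj_eps <- params$lj$eps[match(at$elem, params$lj$element)]
  lj_rmin <- params$lj$rmin[match(at$elem, params$lj$element)]
  if (anyNA(lj_eps))
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(at$elem[is.na(lj_eps)]), collapse = ", "))
  hb_idx <- match(at$elem, params$hbond$element)
  for (a in seq_len(nrow(at))) {
    dx <- pts[, 1] - at$x[a]; dy <- pts[, 2] - at$y[a]; dz <- pts[, 3] - at$z[a]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    r <- pmax(r, 1e-6)
    in_lj <- r <= params$lj_cutoff
    if (any(in_lj)) {
      s <- (lj_rmin[a] / r[in_lj])
      e[in_lj] <- e[in_lj] + lj_eps[a] * (s^12 - 2 * s^6)
    }
    if (!is.na(hb_idx[a])) {
      in_hb <- r <= params$hb_cutoff
      if (any(in_hb)) {
        h <- hb_idx[a]
        s <- params$hbond$r0[h] / r[in_hb]
        ehb <- params$hbond$eps[h] * (2 * s^6 - 3 * s^4)
        ## inverted hydrogen bond: what would be attractive for a polar
        ## probe becomes a penalty for the hydrophobic one
        e[in_hb] <- e[in_hb] + pmax(0, -ehb)
      }
    }
  }
  e
}

#' Hydrophobic probe energy at a single point
#'
#' Sum over atoms of a 12-6 Lennard-Jones term plus a sign-inverted
#' (penalizing, >= 0) hydrogen-bond term for donor/acceptor atoms within
#' range, plus the constant entropy term.  No electrostatics: the probe is
#' neutral, so atomic partial charges never enter.  Beyond the
#' Lennard-Jones cutoff from every atom the value is exactly the entropy
#' constant.
#'
#' @param point numeric length-3 coordinate (angstrom).
#' @param structure atoms.
#' @param params a [default_probe_params()] list.
#' @return energy in kcal/mol.
#' @export
dry_point_energy <- function(point, structure, params = default_probe_params()) {
  stopifnot(length(point) == 3, all(is.finite(point)))
  at <- as_atom_table(structure)
  if (nrow(at) == 0) return(params$delta_s)
  dry_energy_points(matrix(point, nrow = 1), at, params)
}

#' Evaluate the hydrophobic interaction field on a grid
#'
#' Moves the probe to every grid point and records the interaction energy;
#' points inside an atomic core are clamped at `params$core_clamp`.
#'
#' @param structure atoms.
#' @param grid a [build_grid()] spec (defaults to one built from the
#'   structure with default spacing/margin).
#' @param params probe parameters.
#' @param chunk_size points evaluated per block.
#' @return an object of class `hie_field`: the grid plus `values`
#'   (kcal/mol, one per point, x fastest-varying).
#' @export
compute_field <- function(structure, grid = NULL,
                          params = default_probe_params(),
                          chunk_size = 100000L) {
  at <- tryCatch(as_atom_table(structure), error = function(e) e)
  if (inherits(at, "error")) {
    if (is.null(grid)) stop(conditionMessage(at))
    at <- data.frame(elem = character(0), x = numeric(0),
                     y = numeric(0), z = numeric(0))
  }
  if (is.null(grid)) grid <- build_grid(at)
  stopifnot(inherits(grid, "grid_spec"))
  pts <- grid_points(grid)
  vals <- numeric(nrow(pts))
  if (nrow(at) == 0) {
    vals[] <- params$delta_s
  } else {
    for (start in seq(1L, nrow(pts), by = chunk_size)) {
      idx <- start:min(start + chunk_size - 1L, nrow(pts))
      vals[idx] <- dry_energy_points(pts[idx, , drop = FALSE], at, params)
    }
    vals <- pmin(vals, params$core_clamp)
  }
  out <- list(grid = grid, values = vals, params = params)
  class(out) <- "hie_field"
  out
}

#' @export
print.hie_field <- function(x, ...) {
  cat(sprintf("<hie_field> %d points, range [%.3f, %.3f] kcal/mol\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Reduce a hydrophobic field to a scalar interaction energy
#'
#' Strategies:
#' \describe{
#'   \item{sum_below_cutoff}{sum of all point energies strictly below
#'     `cutoff` (default -1 kcal/mol); 0 when no point qualifies.  The
#'     default, approximating the integrated favourable hydrophobic
#'     surface.}
#'   \item{min_point}{the global field minimum.}
#'   \item{sum_local_minima}{sum over 6-neighbour local minima below
#'     `cutoff`.}
#' }
#'
#' @param field an `hie_field`.
#' @param strategy one of the above.
#' @param cutoff qualification threshold in kcal/mol (default -1).
#' @return scalar energy in kcal/mol.
#' @export
aggregate_hie <- function(field, strategy = c("sum_below_cutoff", "min_point",
                                              "sum_local_minima"),
                          cutoff = -1) {
  stopifnot(inherits(field, "hie_field"))
  strategy <- match.arg(strategy)
  v <- field$values
  switch(strategy,
    sum_below_cutoff = {
      q <- v[v < cutoff]
      if (length(q) == 0) 0 else sum(q)
    },
    min_point = min(v),
    sum_local_minima = {
      d <- field$grid$dim
      a <- array(v, dim = d)
      pad <- array(Inf, dim = d + 2)
      pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
      ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
      locmin <- a <= pad[ix - 1, iy, iz] & a <= pad[ix + 1, iy, iz] &
        a <= pad[ix, iy - 1, iz] & a <= pad[ix, iy + 1, iz] &
        a <= pad[ix, iy, iz - 1] & a <= pad[ix, iy, iz + 1]
      q <- a[locmin & a < cutoff]
      if (length(q) == 0) 0 else sum(q)
    })
}

#' Hydrophobic interaction energy efficiency
#'
#' @param hie scalar hydrophobic interaction energy (kcal/mol).
#' @param n_heavy ligand heavy-atom count (>= 1).
#' @return kcal/mol per heavy atom.
#' @export
hie_efficiency <- function(hie, n_heavy) efficiency_normalize(hie, n_heavy)

#' Write a field in OpenDX volumetric text format
#'
#' @param field an `hie_field`.
#' @param path output `.dx` file.
#' @export
write_dx <- function(field, path) {
  stopifnot(inherits(field, "hie_field"))
  g <- field$grid
  d <- g$dim
  ## OpenDX stores z fastest; our values are x fastest
  a <- array(field$values, dim = d)
  vals <- as.vector(aperm(a, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0 0", g$spacing),
    sprintf("delta 0 %.6f 0", g$spacing),
    sprintf("delta 0 0 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vals))
  ), con)
  chunks <- split(vals, ceiling(seq_along(vals) / 3))
  writeLines(vapply(chunks, function(v) paste(sprintf("%.6e", v), collapse = " "),
                    ""), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
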