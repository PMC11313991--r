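#' The nine-ligand hCA II benzenesulfonamide descriptor set
#'
#' The packaged per-ligand basic-property table for the nine
#' benzenesulfonamide inhibitors of human carbonic anhydrase II
#' (PDB entries 6h2z, 6h34, 6h33, 3v7x, 4z1k, 4z1e, 4z0q, 4z1j, 3vbd,
#' ligands 1-9): the FMO2 binding energy `dE_FMO` and ligand efficiency
#' `F2LE`, the pairwise interaction-energy sum `E_INT` and fragment
#' efficiency `FE`, the hydrophobic interaction energy `HIE` and its
#' efficiency `HIE_E`, and `logP`.  Energies in kcal/mol; values are
#' packaged exactly as printed.  These descriptors come from external
#' quantum-chemistry (FMO2 RI-MP2/PCM) and hydrophobic-field calculations
#' and are inputs to this package, not quantities it can regenerate.
#'
#' `n_heavy` is the ligand heavy-atom count, derived once from the mutual
#' consistency of the printed energy/efficiency ratios (each count
#' reproduces FE, F2LE and HIE-E at 1-decimal rounding); ligand structures
#' themselves are not packaged.
#'
#' The experimental label column `dG_exp` is empty: binding free energies
#' (from published inhibition constants) are user-supplied, see
#' [hca2_labels()].
#'
#' @return data.frame with columns `ligand`, `dE_FMO`, `F2LE`, `E_INT`,
#'   `FE`, `HIE`, `HIE_E`, `logP`, `n_heavy`, `dG_exp`.
#' @export
hca2_dataset <- function() {
  data.frame(
    ligand = 1:9,
    dE_FMO = c(-37.6, -53.7, -37.4, -42.7, -61.1, -36.7, -67.6, -70.5, -38.6),
    F2LE   = c(-1.6, -2.1, -1.5, -1.7, -2.5, -1.5, -3.1, -3.2, -1.8),
    E_INT  = c(-173.2, -186.2, -175.5, -173.6, -181.1, -163.2, -180.1, -179.3, -163.8),
    FE     = c(-7.2, -7.2, -7.0, -6.9, -7.5, -6.8, -8.2, -8.2, -7.4),
    HIE    = c(-38.9, -37.9, -28.1, -30.6, -35.0, -24.3, -32.0, -30.2, -34.3),
    HIE_E  = c(-1.6, -1.5, -1.1, -1.2, -1.5, -1.0, -1.5, -1.4, -1.6),
    logP   = c(0.92, -0.01, -0.36, 0.41, -0.28, 0.68, 0.6, 0.32, 0.46),
    n_heavy = c(24L, 26L, 25L, 25L, 24L, 24L, 22L, 22L, 22L),
    dG_exp = NA_real_
  )
}

#' Basic-property declaration for the hCA II descriptor set
#'
#' The four FMO binding-strength estimates are alternative representations
#' of the same physical quantity, so they form one exclusivity group: a
#' generated formula may contain at most one of them.  No descriptor in
#' this set is positive-definite (logP changes sign across the ligands).
#'
#' @return a [basic_properties()] object covering the seven descriptors.
#' @export
hca2_basic_properties <- function() {
  basic_properties(
    name = c("dE_FMO", "F2LE", "E_INT", "FE", "HIE", "HIE_E", "logP"),
    positive_definite = FALSE,
    group = c("fmo", "fmo", "fmo", "fmo", NA, NA, NA)
  )
}

#' Load user-supplied experimental binding free energies
#'
#' Experimental labels for the hCA II set are not distributed with the
#' package; they derive from published inhibition constants and must be
#' supplied by the user as a CSV with columns `ligand` and either `dG_exp`
#' (kcal/mol) or `Ki_M` (molar, converted via [delta_g_from_ki()], with an
#' optional `T_K` temperature column).
#'
#' @param path CSV path.  When `NULL`, a file `hca2_dg_exp.csv` under the
#'   package's `extdata/` is used if present.
#' @param temperature default conversion temperature (K) when the CSV gives
#'   `Ki_M` without `T_K`.
#' @return data.frame `ligand`, `dG_exp`.
#' @export
hca2_labels <- function(path = NULL, temperature = 298.15) {
  if (is.null(path)) {
    path <- system.file("extdata", "hca2_dg_exp.csv", package = "fgscore")
    if (path == "")
      stop("experimental binding free energies are user-supplied and not ",
           "distributed with the package; pass a CSV with columns ",
           "'ligand' and 'dG_exp' (or 'Ki_M')")
  }
  d <- utils::read.csv(path)
  if (!"ligand" %in% names(d)) stop("labels CSV needs a 'ligand' column")
  if (!"dG_exp" %in% names(d)) {
    if (!"Ki_M" %in% names(d))
      stop("labels CSV needs a 'dG_exp' or 'Ki_M' column")
    temp <- if ("T_K" %in% names(d)) d$T_K else temperature
    d$dG_exp <- delta_g_from_ki(d$Ki_M, temp)
  }
  d[, c("ligand", "dG_exp")]
}

#' Specify a synthetic feature table
#'
#' Declares the generating conditions for a synthetic dataset: BP names and
#' uniform sampling bounds, a ground-truth formula (basic feature, weights,
#' slope, intercept) and Gaussian label noise.  The defaults emulate the
#' study conditions of the hCA II analysis: nine samples, three
#' sign-indefinite descriptors with logP-, efficiency- and
#' ligand-efficiency-like ranges, the published formula structure, and
#' 0.3 kcal/mol label noise.
#'
#' @param seed integer random seed; fully determines the output table.
#' @param n_samples number of samples (default 9).
#' @param bps data.frame with columns `name`, `min`, `max`,
#'   `positive_definite`.
#' @param formula ground-truth [basic_feature()].
#' @param weights ground-truth per-term weights.
#' @param m,q ground-truth slope and intercept.
#' @param noise_sd Gaussian label noise, label units (>= 0, default 0.3).
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_samples = 9L,
                           bps = data.frame(
                             name = c("logP", "HIE_E", "F2LE"),
                             min = c(-0.5, -2.0, -3.3),
                             max = c(1.0, -0.9, -1.4),
                             positive_definite = FALSE),
                           formula = hca2_scoring_function()$feature,
                           weights = c(0.7, 0.5, 0.5, 0.4),
                           m = -7.4, q = -13, noise_sd = 0.3) {
  stopifnot(noise_sd >= 0, n_samples >= 1,
            all(c("name", "min", "max") %in% names(bps)))
  out <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              bps = bps, formula = formula, weights = weights,
              m = m, q = q, noise_sd = noise_sd)
  class(out) <- "synthetic_spec"
  out
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic feature table with labels
#'
#' Samples BP values uniformly within the declared bounds, evaluates the
#' ground-truth formula and adds Gaussian noise to form the label.  Samples
#' where the ground-truth denominator is degenerate are resampled (up to
#' 100 attempts each).  The output is a pure function of the spec (and its
#' seed).
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame of BP columns plus `dG_exp`, with attribute
#'   `"truth"` holding the noiseless labels.
#' @export
make_feature_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_samples
    draw <- function(k) {
      ## sample per-BP columns explicitly (one uniform range per BP)
      matrix(stats::runif(k * nrow(spec$bps),
                          rep(spec$bps$min, each = k),
                          rep(spec$bps$max, each = k)),
             nrow = k, dimnames = list(NULL, spec$bps$name))
    }
    tab <- as.data.frame(draw(n))
    ev <- evaluate_feature(spec$formula, tab, spec$weights)
    attempts <- 0
    while (any(ev$invalid)) {
      attempts <- attempts + 1
      if (attempts > 100)
        stop("generation error: degenerate samples persist after 100 resampling attempts")
      bad <- which(ev$invalid)
      tab[bad, ] <- as.data.frame(draw(length(bad)))
      ev <- evaluate_feature(spec$formula, tab, spec$weights)
    }
    truth <- spec$m * ev$values + spec$q
    tab$dG_exp <- truth + stats::rnorm(n, 0, spec$noise_sd)
    attr(tab, "truth") <- truth
    tab
  })
}

#' Emit a PIEDA text fixture with known ground truth
#'
#' Writes a dialect-conformant FMO2/PIEDA output section (the
#' `"gamess-fmo"` dialect that [parse_pieda_output()] reads) whose parsed
#' content equals the returned ground-truth table exactly.  Fragments are
#' residues plus (for three or more fragments) a metal ion, with the
#' ligand last; pairs cover ligand-partner interactions and nearest
#' residue-residue contacts.  Components are drawn at 3-decimal resolution
#' and the totals are their exact sums, so the decomposition closes
#' exactly.  The first residue is built dispersion-dominated (its most
#' negative component is the dispersion term).
#'
#' @param n_fragments total number of fragments (>= 2).
#' @param seed integer seed.
#' @param path optional file to write; when `NULL` only text is returned.
#' @param ligand_totals optional numeric vector (length `n_fragments - 1`)
#'   of ligand-pair PIE totals to impose, e.g. to fix their sum.
#' @return list with `text` (character lines), `table` (ground-truth
#'   `pieda_table`), `path`.
#' @export
make_pieda_fixture <- function(n_fragments, seed = 1L, path = NULL,
                               ligand_totals = NULL) {
  stopifnot(n_fragments >= 2)
  with_seed(seed, {
    n <- n_fragments
    has_metal <- n >= 3
    n_res <- n - 1L - has_metal
    frags <- data.frame(
      id = seq_len(n),
      label = c(if (n_res > 0) paste0("GLY", seq_len(n_res) * 10),
                if (has_metal) "ZN", "LIG"),
      role = c(rep("residue", n_res), if (has_metal) "metal", "ligand"),
      stringsAsFactors = FALSE
    )
    lig <- as.integer(n)
    partners <- seq_len(n - 1L)
    rnd3 <- function(k, lo, hi) round(stats::runif(k, lo, hi), 3)
    mk_components <- function(k, disp_heavy = FALSE) {
      data.frame(
        es = rnd3(k, -8, 2), ex = rnd3(k, 0, 3), ct = rnd3(k, -3, 0),
        disp = if (disp_heavy) rnd3(k, -12, -9) else rnd3(k, -3, 0),
        sol = rnd3(k, -2, 2)
      )
    }
    comp <- mk_components(length(partners))
    comp[1, ] <- mk_components(1, disp_heavy = TRUE)
    recs <- data.frame(i = partners, j = lig, comp)
    if (!is.null(ligand_totals)) {
      stopifnot(length(ligand_totals) == length(partners))
      ## absorb the adjustment into the electrostatic component
      cur <- with(recs, es + ex + ct + disp + sol)
      recs$es <- round(recs$es + round(ligand_totals, 3) - cur, 3)
    }
    if (n_res >= 2) {
      rr <- data.frame(i = seq_len(n_res - 1L), j = seq_len(n_res - 1L) + 1L,
                       mk_components(n_res - 1L))
      recs <- rbind(recs, rr)
    }
    recs$total <- with(recs, round(es + ex + ct + disp + sol, 3))
    recs <- recs[, c("i", "j", "total", "es", "ex", "ct", "disp", "sol")]

    text <- c(
      "          PIEDA INTERACTION ANALYSIS",
      "          ==========================",
      " THEORY= RI-MP2/6-311G  BASIS= 6-311G  UNITS= KCAL/MOL",
      "",
      " FRAGMENT LIST",
      "   FRG   NAME       ROLE",
      sprintf("  %4d   %-8s   %s", frags$id, frags$label, frags$role),
      "",
      " PAIR INTERACTION ENERGY DECOMPOSITION (KCAL/MOL)",
      sprintf("  %4s %4s %10s %10s %10s %10s %10s %10s",
              "I", "J", "TOTAL", "ES", "EX", "CT", "DISP", "SOL"),
      sprintf("  %4d %4d %10.3f %10.3f %10.3f %10.3f %10.3f %10.3f",
              recs$i, recs$j, recs$total, recs$es, recs$ex, recs$ct,
              recs$disp, recs$sol),
      " END PIEDA"
    )
    if (!is.null(path)) writeLines(text, path)
    truth <- list(records = recs, fragments = frags,
                  theory = "RI-MP2/6-311G", basis = "6-311G",
                  dialect = "gamess-fmo")
    class(truth) <- "pieda_table"
    list(text = text, table = truth, path = path)
  })
}

#' Emit a minimal PDB fixture with exactly specified coordinates
#'
#' Three deterministic layouts support the pocket-reduction tests:
#' \describe{
#'   \item{three_residue_shell}{a one-atom ligand at the origin surrounded
#'     by three glycine residues whose minimum heavy-atom distances to the
#'     ligand are exactly 4.0, 5.9 and 7.0 angstrom, plus a zinc ion.}
#'   \item{tripeptide}{a contiguous three-residue glycine chain (backbone
#'     N, CA, C, O only; add `complete_termini = TRUE` for an N-terminal
#'     hydrogen and OXT).}
#'   \item{two_ring_ligand}{a two-ring ligand: a benzenesulfonamide-like
#'     head (ring + SO2N) joined by a single inter-ring bond to a second
#'     benzene ring.}
#' }
#'
#' @param layout one of the three layout names.
#' @param path optional file to write.
#' @param complete_termini tripeptide only: include the terminal H and OXT.
#' @return list `text` (PDB lines), `path`.
#' @export
make_pdb_fixture <- function(layout = c("three_residue_shell", "tripeptide",
                                        "two_ring_ligand"),
                             path = NULL, complete_termini = FALSE) {
  layout <- match.arg(layout)
  rec <- function(serial, name, resid, chain, resno, x, y, z, elem,
                  het = FALSE) {
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (het) "HETATM" else "ATOM", serial,
            if (nchar(name) < 4) paste0(" ", name) else name,
            resid, chain, resno, x, y, z, 1.00, 0.00, elem)
  }
  lines <- switch(layout,
    three_residue_shell = {
      s <- 0L; out <- character(0)
      add <- function(name, resid, chain, resno, x, y, z, elem, het = FALSE) {
        s <<- s + 1L
        out <<- c(out, rec(s, name, resid, chain, resno, x, y, z, elem, het))
      }
      add("C1", "LIG", "A", 101, 0, 0, 0, "C", het = TRUE)
      ## closest atom of each residue pinned at the target distance
      add("N", "GLY", "A", 1, 5.2, 0.8, 0.0, "N")
      add("CA", "GLY", "A", 1, 4.0, 0.0, 0.0, "C")
      add("C", "GLY", "A", 1, 5.0, -1.2, 0.0, "C")
      add("N", "GLY", "A", 2, 0.8, 7.1, 0.0, "N")
      add("CA", "GLY", "A", 2, 0.0, 5.9, 0.0, "C")
      add("C", "GLY", "A", 2, -0.9, 7.0, 0.0, "C")
      add("N", "GLY", "A", 3, 0.8, 0.8, 8.1, "N")
      add("CA", "GLY", "A", 3, 0.0, 0.0, 7.0, "C")
      add("C", "GLY", "A", 3, -0.9, 0.3, 8.1, "C")
      add("ZN", "ZN", "A", 201, 0.0, 0.0, 2.1, "ZN", het = TRUE)
      out
    },
    tripeptide = {
      s <- 0L; out <- character(0)
      add <- function(name, resno, x, y, z, elem) {
        s <<- s + 1L
        out <<- c(out, rec(s, name, "GLY", "A", resno, x, y, z, elem))
      }
      for (i in 0:2) {
        t <- i * 3.3
        add("N", i + 1, t, 0, 0, "N")
        add("CA", i + 1, t + 1.45, 0, 0, "C")
        add("C", i + 1, t + 2.2, 1.2, 0, "C")
        add("O", i + 1, t + 2.0, 2.4, 0, "O")
      }
      if (complete_termini) {
        add("H", 1, -0.6, -0.8, 0, "H")
        add("OXT", 3, 6.6 + 3.2, 1.4, 0, "O")
      }
      out
    },
    two_ring_ligand = {
      s <- 0L; out <- character(0)
      add <- function(name, x, y, z, elem) {
        s <<- s + 1L
        out <<- c(out, rec(s, name, "LIG", "A", 1, x, y, z, elem, het = TRUE))
      }
      hex <- function(cx, prefix, start) {
        for (k in 0:5) {
          a <- k * pi / 3
          add(paste0(prefix, start + k), cx + 1.4 * cos(a), 1.4 * sin(a), 0, "C")
        }
      }
      hex(0, "C", 1)                       # head ring, C1 at (1.4, 0, 0)
      add("S1", 3.2, 0, 0, "S")            # C1-S 1.8
      add("O1", 3.2, 1.43, 0, "O")
      add("O2", 3.2, -1.43, 0, "O")
      add("N1", 4.8, 0, 0, "N")            # S-N 1.6
      hex(-4.2, "C", 7)                    # tail ring, C7 at (-2.8, 0, 0)
      out
    })
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  list(text = lines, path = path)
}

#' Manually construct a pocket selection
#'
#' Mostly useful in tests and scripts when a selection is known a priori
#' rather than computed by [select_pocket()].
#'
#' @param chain,resno,insert,resid vectors describing the residues.
#' @param cutoff recorded cutoff attribute.
#' @param source recorded source attribute.
#' @return a `pocket_selection`.
#' @export
pocket_selection <- function(chain, resno, insert = "", resid = "UNK",
                             cutoff = NA_real_, source = "manual") {
  n <- length(resno)
  out <- data.frame(chain = rep_len(chain, n), resno = resno,
                    insert = rep_len(insert, n), resid = rep_len(resid, n),
                    min_dist = NA_real_, stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$chain, out$resno, out$insert)))
    stop("residue identifiers must be unique")
  attr(out, "cutoff") <- cutoff
  attr(out, "source") <- source
  class(out) <- c("pocket_selection", "data.frame")
  out
}
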