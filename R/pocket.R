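## covalent radii (angstrom) for bond perception, and the known-element list
COVALENT_RADII <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57, NA. = 1.66,
  MG = 1.41, P = 1.07, S = 1.05, CL = 1.02, K = 2.03, CA = 1.76, MN = 1.39,
  FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32, ZN = 1.22, BR = 1.20, I = 1.39,
  SE = 1.20
)
names(COVALENT_RADII)[names(COVALENT_RADII) == "NA."] <- "NA"
KNOWN_ELEMENTS <- names(COVALENT_RADII)
METAL_ELEMENTS <- c("ZN", "MG", "MN", "FE", "CO", "NI", "CU", "CA", "NA", "K")
WATER_RESIDUES <- c("HOH", "WAT", "H2O", "DOD")

#' Construct a ligand-receptor complex structure
#'
#' Normalizes an atom table into the container the pocket operations work
#' on.  Each atom is classified as `residue`, `ligand`, `metal` or `water`
#' from its residue name and element.
#'
#' @param atoms data.frame with columns `serial`, `elety` (atom name),
#'   `resid` (residue name), `chain`, `resno`, `x`, `y`, `z`, `elem`, and
#'   optionally `insert` and `o` (occupancy).
#' @param ligand_resname residue name(s) identifying the ligand.
#' @param metal_elements element symbols treated as catalytic metal ions.
#' @param keep_waters retain water molecules (default `FALSE`; crystal
#'   waters are removed before fragment analysis by default).
#' @param source free-text provenance tag.
#' @return an object of class `complex_structure`.
#' @export
complex_structure <- function(atoms, ligand_resname,
                              metal_elements = METAL_ELEMENTS,
                              keep_waters = FALSE, source = "") {
  need <- c("elety", "resid", "chain", "resno", "x", "y", "z", "elem")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  if (!"o" %in% names(atoms)) atoms$o <- 1
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$elem <- toupper(trimws(atoms$elem))
  unknown <- setdiff(unique(atoms$elem), KNOWN_ELEMENTS)
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  atoms$type <- ifelse(toupper(atoms$resid) %in% toupper(ligand_resname), "ligand",
                ifelse(toupper(atoms$resid) %in% WATER_RESIDUES, "water",
                ifelse(atoms$elem %in% metal_elements &
                         toupper(atoms$resid) %in% c(metal_elements, "ZN2", "MG2"),
                       "metal", "residue")))
  if (!keep_waters) atoms <- atoms[atoms$type != "water", , drop = FALSE]
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, ligand_resname = ligand_resname, source = source)
  class(out) <- "complex_structure"
  out
}

#' @export
print.complex_structure <- function(x, ...) {
  tb <- table(x$atoms$type)
  cat("<complex_structure> ", nrow(x$atoms), " atoms (",
      paste(names(tb), tb, sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read a ligand-receptor complex from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()].  Alternate-location conformers
#' are resolved by keeping the highest-occupancy copy of each atom; waters
#' are dropped unless requested.
#'
#' @param path PDB file path.
#' @inheritParams complex_structure
#' @return a `complex_structure`.
#' @export
read_complex <- function(path, ligand_resname,
                         metal_elements = METAL_ELEMENTS, keep_waters = FALSE) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = a$eleno, elety = a$elety, resid = a$resid, chain = a$chain,
    resno = a$resno, insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    elem = ifelse(is.na(a$elesy) | a$elesy == "", guess_element(a$elety), a$elesy),
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE
  )
  ## altloc: keep the highest-occupancy conformer of each named atom
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
    i[which.max(atoms$o[i])]
  }), use.names = FALSE)
  atoms <- atoms[sort(keep), , drop = FALSE]
  complex_structure(atoms, ligand_resname, metal_elements, keep_waters,
                    source = path)
}

guess_element <- function(elety) {
  e <- toupper(gsub("[^A-Za-z].*", "", trimws(elety)))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% c("ZN", "MG", "FE", "CL", "BR", "NA", "MN", "CU", "NI", "SE"),
         two, one)
}

#' Select binding-pocket residues within a distance of the ligand
#'
#' A residue is selected iff the minimum distance between any of its atoms
#' (hydrogens excluded by default, since deposited crystal structures
#' usually lack them) and any ligand atom is at most `cutoff`.  The metal
#' ion is always retained, tracked separately from the residue selection.
#'
#' @param cs a `complex_structure` with a non-empty ligand.
#' @param cutoff distance cutoff in angstrom (> 0; 6 is the conventional
#'   binding-pocket radius).
#' @param include_h include hydrogens in the distance criterion.
#' @return an object of class `pocket_selection`: data.frame with `chain`,
#'   `resno`, `insert`, `resid`, `min_dist`; attributes `cutoff`, `source`.
#' @export
select_pocket <- function(cs, cutoff = 6, include_h = FALSE) {
  stopifnot(inherits(cs, "complex_structure"))
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  at <- cs$atoms
  lig <- at[at$type == "ligand", , drop = FALSE]
  if (!include_h) lig <- lig[lig$elem != "H", , drop = FALSE]
  if (nrow(lig) == 0)
    stop("structural input error: complex has no ligand atoms (resname ",
         paste(cs$ligand_resname, collapse = "/"), ")")
  res <- at[at$type == "residue", , drop = FALSE]
  if (!include_h) res <- res[res$elem != "H", , drop = FALSE]
  if (nrow(res) == 0) {
    sel <- data.frame(chain = character(0), resno = integer(0),
                      insert = character(0), resid = character(0),
                      min_dist = numeric(0), stringsAsFactors = FALSE)
  } else {
    key <- paste(res$chain, res$resno, res$insert)
    lx <- as.matrix(lig[, c("x", "y", "z")])
    mind <- vapply(split(seq_len(nrow(res)), key), function(i) {
      rx <- as.matrix(res[i, c("x", "y", "z")])
      d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * rx %*% t(lx)
      sqrt(max(0, min(d2)))
    }, numeric(1))
    first <- !duplicated(key)
    ord <- res[first, c("chain", "resno", "insert", "resid")]
    ord$min_dist <- mind[match(paste(ord$chain, ord$resno, ord$insert),
                               names(mind))]
    sel <- ord[ord$min_dist <= cutoff, , drop = FALSE]
    sel <- sel[order(sel$chain, sel$resno, sel$insert), , drop = FALSE]
  }
  rownames(sel) <- NULL
  attr(sel, "cutoff") <- cutoff
  attr(sel, "source") <- cs$source
  class(sel) <- c("pocket_selection", "data.frame")
  sel
}

#' Union of pocket selections across complexes
#'
#' Combines residue selections computed on several complexes that share a
#' residue-numbering scheme into their set union, so the same reduced
#' binding core can be used for every complex.  Selections whose residue
#' names disagree at a shared (chain, number, insertion) position indicate
#' mismatched numbering and raise an error rather than silently
#' renumbering.
#'
#' @param selections non-empty list of `pocket_selection` objects.
#' @return a `pocket_selection` with source `"union"`.
#' @export
union_pockets <- function(selections) {
  if (!is.list(selections) || length(selections) == 0)
    stop("union_pockets needs a non-empty list of selections")
  if (!all(vapply(selections, inherits, TRUE, "pocket_selection")))
    stop("all elements must be pocket_selection objects")
  all <- do.call(rbind, lapply(selections, function(s) {
    as.data.frame(s)[, c("chain", "resno", "insert", "resid")]
  }))
  key <- paste(all$chain, all$resno, all$insert)
  name_per_key <- tapply(all$resid, key, function(v) length(unique(v)))
  if (any(name_per_key > 1))
    stop("mismatched residue numbering across complexes: position(s) ",
         paste(names(name_per_key)[name_per_key > 1], collapse = ", "),
         " carry different residue names")
  u <- all[!duplicated(key), , drop = FALSE]
  u <- u[order(u$chain, u$resno, u$insert), , drop = FALSE]
  u$min_dist <- NA_real_
  rownames(u) <- NULL
  attr(u, "cutoff") <- attr(selections[[1]], "cutoff")
  attr(u, "source") <- "union"
  class(u) <- c("pocket_selection", "data.frame")
  u
}

sel_key <- function(df) paste(df$chain, df$resno, df$insert)

#' Build a hydrogen-capped reduced complex from a pocket selection
#'
#' Restricts a complex to the selected residues plus the ligand and metal,
#' and caps every backbone bond severed by the selection with a hydrogen
#' placed along the former bond vector (N-H 1.01, C-H 1.09 angstrom; no
#' geometry optimization).  Chain-terminal residues are capped too when
#' their terminal groups are incomplete (no hydrogen on N, no OXT on C).
#' Emits the fragment annotation used by FMO input preparation: one
#' fragment per residue, the metal as its own fragment, the ligand as one
#' fragment.
#'
#' @param cs the full `complex_structure`.
#' @param selection a `pocket_selection` (typically the union across
#'   complexes).
#' @return an object of class `reduced_complex`: `atoms` (selected atoms
#'   plus capping hydrogens, each with a `fragment` id), `caps` (one row
#'   per added hydrogen with the severed bond it replaces), `fragments`
#'   (id, label, type).
#' @export
cap_termini <- function(cs, selection) {
  stopifnot(inherits(cs, "complex_structure"),
            inherits(selection, "pocket_selection"))
  at <- cs$atoms
  res_at <- at[at$type == "residue", , drop = FALSE]
  have <- unique(sel_key(res_at))
  want <- sel_key(selection)
  if (!all(want %in% have))
    stop("selection contains residue(s) absent from the structure: ",
         paste(setdiff(want, have), collapse = ", "))

  keep <- at$type %in% c("ligand", "metal") |
    (at$type == "residue" & sel_key(at) %in% want)
  red <- at[keep, , drop = FALSE]

  get_atom <- function(chain, resno, insert, name) {
    r <- at[at$chain == chain & at$resno == resno & at$insert == insert &
              at$elety == name, , drop = FALSE]
    if (nrow(r) == 0) NULL else r[1, ]
  }
  has_h_on <- function(chain, resno, insert, name, rmax = 1.3) {
    a <- get_atom(chain, resno, insert, name)
    if (is.null(a)) return(FALSE)
    h <- at[at$chain == chain & at$resno == resno & at$insert == insert &
              at$elem == "H", , drop = FALSE]
    if (nrow(h) == 0) return(FALSE)
    any(sqrt((h$x - a$x)^2 + (h$y - a$y)^2 + (h$z - a$z)^2) <= rmax)
  }
  unit_to <- function(from, to) {
    v <- c(to$x - from$x, to$y - from$y, to$z - from$z)
    v / sqrt(sum(v^2))
  }

  caps <- list()
  add_cap <- function(site, direction, length, replaces, fragment) {
    pos <- c(site$x, site$y, site$z) + length * direction
    caps[[length(caps) + 1]] <<- data.frame(
      chain = site$chain, resno = site$resno, insert = site$insert,
      site_atom = site$elety, x = pos[1], y = pos[2], z = pos[3],
      replaces = replaces, fragment = fragment, stringsAsFactors = FALSE
    )
  }

  NH <- 1.01; CH <- 1.09; PEPTIDE_MAX <- 1.8
  sel_rows <- as.data.frame(selection)
  for (r in seq_len(nrow(sel_rows))) {
    ch <- sel_rows$chain[r]; rn <- sel_rows$resno[r]; ins <- sel_rows$insert[r]
    frag <- r
    aN <- get_atom(ch, rn, ins, "N")
    aC <- get_atom(ch, rn, ins, "C")
    aCA <- get_atom(ch, rn, ins, "CA")
    if (is.null(aN) || is.null(aC) || is.null(aCA))
      warning("residue ", sel_rows$resid[r], " ", ch, rn,
              " has missing backbone atoms; capped where possible")
    ## N side: severed peptide bond to the preceding residue, or an
    ## incomplete chain-start amine
    prevC <- get_atom(ch, rn - 1, "", "C")
    if (!is.null(aN)) {
      if (!is.null(prevC) &&
          sqrt(sum((c(prevC$x, prevC$y, prevC$z) - c(aN$x, aN$y, aN$z))^2)) <= PEPTIDE_MAX) {
        if (!paste(ch, rn - 1, "") %in% want)
          add_cap(aN, unit_to(aN, prevC), NH,
                  sprintf("peptide C(%d)-N(%d)", rn - 1, rn), frag)
      } else if (!has_h_on(ch, rn, ins, "N")) {
        if (!is.null(aCA)) add_cap(aN, unit_to(aCA, aN), NH,
                                   sprintf("chain-start N(%d)", rn), frag)
      }
    }
    ## C side: severed peptide bond to the following residue, or an
    ## incomplete chain-end carbonyl
    nextN <- get_atom(ch, rn + 1, "", "N")
    if (!is.null(aC)) {
      if (!is.null(nextN) &&
          sqrt(sum((c(nextN$x, nextN$y, nextN$z) - c(aC$x, aC$y, aC$z))^2)) <= PEPTIDE_MAX) {
        if (!paste(ch, rn + 1, "") %in% want)
          add_cap(aC, unit_to(aC, nextN), CH,
                  sprintf("peptide C(%d)-N(%d)", rn, rn + 1), frag)
      } else if (is.null(get_atom(ch, rn, ins, "OXT")) &&
                 !has_h_on(ch, rn, ins, "C")) {
        if (!is.null(aCA)) add_cap(aC, unit_to(aCA, aC), CH,
                                   sprintf("chain-end C(%d)", rn), frag)
      }
    }
  }
  caps <- if (length(caps)) do.call(rbind, caps) else data.frame(
    chain = character(0), resno = integer(0), insert = character(0),
    site_atom = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
    replaces = character(0), fragment = integer(0), stringsAsFactors = FALSE
  )

  ## fragment annotation: residues in selection order, then metal, then ligand
  n_res <- nrow(sel_rows)
  has_metal <- any(red$type == "metal")
  frags <- data.frame(
    id = seq_len(n_res + has_metal + 1L),
    label = c(paste0(sel_rows$resid, sel_rows$resno),
              if (has_metal) red$elem[red$type == "metal"][1],
              paste(cs$ligand_resname, collapse = "+")),
    type = c(rep("residue", n_res), if (has_metal) "metal", "ligand"),
    stringsAsFactors = FALSE
  )
  red$fragment <- NA_integer_
  ridx <- red$type == "residue"
  red$fragment[ridx] <- match(sel_key(red[ridx, ]), want)
  red$fragment[red$type == "metal"] <- n_res + 1L
  red$fragment[red$type == "ligand"] <- n_res + has_metal + 1L

  if (nrow(caps)) {
    cap_atoms <- data.frame(
      serial = max(red$serial) + seq_len(nrow(caps)),
      elety = "HCP", resid = "CAP", chain = caps$chain, resno = caps$resno,
      insert = caps$insert, x = caps$x, y = caps$y, z = caps$z, o = 1,
      elem = "H", type = "residue", fragment = caps$fragment,
      stringsAsFactors = FALSE
    )
    red <- rbind(red[, names(cap_atoms)], cap_atoms)
  } else red <- red[, c("serial", "elety", "resid", "chain", "resno", "insert",
                        "x", "y", "z", "o", "elem", "type", "fragment")]
  rownames(red) <- NULL
  out <- list(atoms = red, caps = caps, fragments = frags,
              selection = selection, source = cs$source)
  class(out) <- "reduced_complex"
  out
}

#' @export
print.reduced_complex <- function(x, ...) {
  cat(sprintf("<reduced_complex> %d fragments (%d residues%s + ligand), %d atoms, %d caps\n",
              nrow(x$fragments), sum(x$fragments$type == "residue"),
              if (any(x$fragments$type == "metal")) " + metal" else "",
              nrow(x$atoms), nrow(x$caps)))
  invisible(x)
}

## distance-based bond perception over an atom table
perceive_bonds <- function(atoms, slack = 0.45) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  r <- COVALENT_RADII[atoms$elem]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(r, r, "+") + slack
  hit <- which(d <= thr & upper.tri(d) & d > 0.1, arr.ind = TRUE)
  unname(hit)
}

#' Split a ligand into head and tail fragments at a bond
#'
#' Deletes the given single bond between two heavy atoms and partitions the
#' ligand into the two resulting connected components: F1, the metal-binding
#' head (identified as the component containing a sulfonamide sulfur, or
#' the component containing `anchor` when no sulfonamide is present), and
#' F2, the tail.  F1's cut valence is capped with a hydrogen, F2's with a
#' methyl group.
#'
#' @param ligand a `complex_structure` (its ligand atoms are used) or an
#'   atom data.frame.
#' @param split_bond length-2 vector of atom serial numbers defining the
#'   bond to cut.
#' @param anchor optional serial of an atom known to belong to F1, used
#'   when no sulfonamide sulfur exists.
#' @return an object of class `ligand_split`: `f1`, `f2` (atom tables
#'   including caps), `split_bond`, `caps` description, and the pre-capping
#'   heavy-atom counts.
#' @export
split_ligand <- function(ligand, split_bond, anchor = NULL) {
  atoms <- if (inherits(ligand, "complex_structure"))
    ligand$atoms[ligand$atoms$type == "ligand", , drop = FALSE]
  else as_atom_table(ligand)
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  if (nrow(atoms) < 2) stop("ligand has fewer than 2 atoms")
  stopifnot(length(split_bond) == 2)
  i <- match(split_bond[1], atoms$serial)
  j <- match(split_bond[2], atoms$serial)
  if (is.na(i) || is.na(j)) stop("split-bond atom serial(s) not in ligand")
  if (atoms$elem[i] == "H" || atoms$elem[j] == "H")
    stop("split bond must connect two heavy atoms")

  bonds <- perceive_bonds(atoms)
  is_split <- (bonds[, 1] == i & bonds[, 2] == j) |
    (bonds[, 1] == j & bonds[, 2] == i)
  if (!any(is_split)) stop("split-bond atoms are not bonded")
  bonds2 <- bonds[!is_split, , drop = FALSE]

  ## connected components after bond deletion
  comp <- seq_len(nrow(atoms))
  repeat {
    new <- comp
    for (b in seq_len(nrow(bonds2))) {
      m <- min(new[bonds2[b, 1]], new[bonds2[b, 2]])
      new[bonds2[b, 1]] <- m; new[bonds2[b, 2]] <- m
    }
    if (identical(new, comp)) break
    comp <- new
  }
  if (comp[i] == comp[j])
    stop("bond lies in a ring: deleting it does not bipartition the ligand")

  ## F1 = component with a sulfonamide S (S bonded to >= 2 O and >= 1 N)
  f1_comp <- NA
  s_idx <- which(atoms$elem == "S")
  for (s in s_idx) {
    nb <- c(bonds[bonds[, 1] == s, 2], bonds[bonds[, 2] == s, 1])
    if (sum(atoms$elem[nb] == "O") >= 2 && sum(atoms$elem[nb] == "N") >= 1) {
      f1_comp <- comp[s]; break
    }
  }
  if (is.na(f1_comp) && length(s_idx)) f1_comp <- comp[s_idx[1]]
  if (is.na(f1_comp)) {
    if (is.null(anchor)) stop("no sulfonamide sulfur found; supply 'anchor'")
    ai <- match(anchor, atoms$serial)
    if (is.na(ai)) stop("anchor serial not in ligand")
    f1_comp <- comp[ai]
  }
  f1_idx <- which(comp == f1_comp)
  f2_idx <- which(comp == comp[if (comp[i] == f1_comp) j else i])
  if (!setequal(c(f1_idx, f2_idx), seq_len(nrow(atoms))))
    stop("ligand has more than two components; is it one connected molecule?")

  a1 <- if (comp[i] == f1_comp) i else j  # F1-side atom of the cut bond
  a2 <- if (a1 == i) j else i
  u12 <- c(atoms$x[a2] - atoms$x[a1], atoms$y[a2] - atoms$y[a1],
           atoms$z[a2] - atoms$z[a1])
  u12 <- u12 / sqrt(sum(u12^2))

  next_serial <- max(atoms$serial)
  mk_atom <- function(elem, pos, name) {
    next_serial <<- next_serial + 1
    data.frame(serial = next_serial, elety = name, resid = "CAP",
               chain = atoms$chain[1], resno = atoms$resno[1],
               insert = "", x = pos[1], y = pos[2], z = pos[3], o = 1,
               elem = elem, stringsAsFactors = FALSE)
  }
  cols <- c("serial", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "elem")
  for (cc in setdiff(cols, names(atoms)))
    atoms[[cc]] <- switch(cc, resid = "LIG", chain = "A", resno = 1L,
                          insert = "", o = 1, elety = atoms$elem)
  f1 <- atoms[f1_idx, cols]
  f2 <- atoms[f2_idx, cols]

  p1 <- c(atoms$x[a1], atoms$y[a1], atoms$z[a1])
  f1 <- rbind(f1, mk_atom("H", p1 + 1.09 * u12, "HCP"))

  p2 <- c(atoms$x[a2], atoms$y[a2], atoms$z[a2])
  cpos <- p2 - 1.50 * u12
  f2 <- rbind(f2, mk_atom("C", cpos, "CCP"))
  ## three methyl hydrogens on a tetrahedral frame about the new C
  ref <- if (abs(u12[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u12) * u12; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u12[2] * e1[3] - u12[3] * e1[2],
          u12[3] * e1[1] - u12[1] * e1[3],
          u12[1] * e1[2] - u12[2] * e1[1])
  for (k in 0:2) {
    ang <- 2 * pi * k / 3
    dir <- -u12 * cos(70.5 * pi / 180) +
      sin(70.5 * pi / 180) * (cos(ang) * e1 + sin(ang) * e2)
    f2 <- rbind(f2, mk_atom("H", cpos + 1.09 * dir, "HCP"))
  }
  rownames(f1) <- rownames(f2) <- NULL
  out <- list(
    f1 = f1, f2 = f2,
    split_bond = atoms$serial[c(a1, a2)],
    caps = c(f1 = "H", f2 = "CH3"),
    n_heavy_f1 = sum(atoms$elem[f1_idx] != "H"),
    n_heavy_f2 = sum(atoms$elem[f2_idx] != "H")
  )
  class(out) <- "ligand_split"
  out
}

#' @export
print.ligand_split <- function(x, ...) {
  cat(sprintf("<ligand_split> F1: %d atoms (H-capped), F2: %d atoms (CH3-capped); bond %d-%d\n",
              nrow(x$f1), nrow(x$f2), x$split_bond[1], x$split_bond[2]))
  invisible(x)
}

#' Count heavy (non-hydrogen) atoms
#'
#' Accepts an atom table, a `complex_structure` (ligand atoms only counted
#' when `ligand_only = TRUE`), a molecular formula string such as
#' `"C6H7NO2S"`, or a character vector of element symbols.
#'
#' @param x the structure, formula or element vector.
#' @param ... passed to methods.
#' @return integer count of non-hydrogen atoms.
#' @export
count_heavy_atoms <- function(x, ...) UseMethod("count_heavy_atoms")

#' @rdname count_heavy_atoms
#' @param ligand_only for `complex_structure`: count only ligand atoms.
#' @export
count_heavy_atoms.complex_structure <- function(x, ligand_only = FALSE, ...) {
  a <- x$atoms
  if (ligand_only) a <- a[a$type == "ligand", , drop = FALSE]
  sum(a$elem != "H")
}

#' @rdname count_heavy_atoms
#' @export
count_heavy_atoms.data.frame <- function(x, ...) {
  a <- as_atom_table(x)
  bad <- setdiff(unique(a$elem), KNOWN_ELEMENTS)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  sum(a$elem != "H")
}

#' @rdname count_heavy_atoms
#' @export
count_heavy_atoms.character <- function(x, ...) {
  if (length(x) == 1 && grepl("[0-9]", x) || (length(x) == 1 && nchar(x) > 3)) {
    ## molecular formula
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
    toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x))
      stop("cannot parse molecular formula: ", x)
    total <- 0L
    for (t in toks) {
      el <- toupper(gsub("[0-9]", "", t))
      cnt <- gsub("[^0-9]", "", t)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!el %in% KNOWN_ELEMENTS) stop("unknown element symbol: ", el)
      if (el != "H") total <- total + cnt
    }
    return(total)
  }
  el <- toupper(x)
  bad <- setdiff(unique(el), KNOWN_ELEMENTS)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  sum(el != "H")
}

#' @rdname count_heavy_atoms
#' @export
count_heavy_atoms.ligand_split <- function(x, ...) {
  c(f1 = x$n_heavy_f1, f2 = x$n_heavy_f2)
}

#' Write a reduced complex to PDB with a fragment-annotation sidecar
#'
#' @param rc a `reduced_complex`.
#' @param pdb_path output PDB path.
#' @param json_path optional sidecar path (default: `pdb_path` with
#'   `.json`); maps each fragment id to its atom serials and type.
#' @export
write_reduced <- function(rc, pdb_path, json_path = NULL) {
  stopifnot(inherits(rc, "reduced_complex"))
  a <- rc$atoms
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   eleno = a$serial, elety = a$elety, o = a$o,
                   elesy = a$elem)
  if (is.null(json_path)) json_path <- sub("\\.pdb$", ".json", pdb_path)
  ann <- lapply(seq_len(nrow(rc$fragments)), function(i) {
    list(id = rc$fragments$id[i], label = rc$fragments$label[i],
         type = rc$fragments$type[i],
         atoms = a$serial[!is.na(a$fragment) & a$fragment == rc$fragments$id[i]])
  })
  jsonlite::write_json(ann, json_path, auto_unbox = TRUE, digits = NA)
  invisible(pdb_path)
}
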