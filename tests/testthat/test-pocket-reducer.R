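test_that("pocket selection applies the distance cutoff exactly", {
  cs <- fixture_complex("three_residue_shell")
  sel <- select_pocket(cs, 6)
  expect_equal(sel$resno, c(1L, 2L))
  expect_equal(sel$min_dist, c(4.0, 5.9), tolerance = 1e-6)
  # the 7 A residue enters at a wider cutoff
  expect_equal(select_pocket(cs, 7.5)$resno, 1:3)
  expect_error(select_pocket(cs, 0), "cutoff")
  expect_error(select_pocket(cs, -2), "cutoff")
})

test_that("selection equals the brute-force all-pairs scan on random fixtures", {
  set.seed(77)
  for (rep in 1:5) {
    nres <- sample(3:6, 1)
    atoms <- data.frame(
      serial = 1, elety = "C1", resid = "LIG", chain = "A", resno = 500L,
      x = 0, y = 0, z = 0, elem = "C"
    )
    for (r in seq_len(nres)) {
      k <- sample(2:4, 1)
      atoms <- rbind(atoms, data.frame(
        serial = nrow(atoms) + seq_len(k), elety = paste0("C", seq_len(k)),
        resid = "GLY", chain = "A", resno = r,
        x = runif(k, -9, 9), y = runif(k, -9, 9), z = runif(k, -9, 9),
        elem = "C"
      ))
    }
    cs <- complex_structure(atoms, "LIG")
    for (cutoff in c(4, 6, 8)) {
      got <- sort(paste(select_pocket(cs, cutoff)$chain,
                        select_pocket(cs, cutoff)$resno,
                        select_pocket(cs, cutoff)$insert))
      expect_equal(got, oracle_select(cs, cutoff))
    }
    # monotonicity: tighter cutoffs select subsets
    s4 <- select_pocket(cs, 4); s8 <- select_pocket(cs, 8)
    expect_true(all(paste(s4$chain, s4$resno) %in% paste(s8$chain, s8$resno)))
  }
})

test_that("a ligand-only structure yields an empty selection", {
  atoms <- data.frame(serial = 1:2, elety = c("C1", "C2"), resid = "LIG",
                      chain = "A", resno = 1L, x = c(0, 1.4), y = 0, z = 0,
                      elem = "C")
  cs <- complex_structure(atoms, "LIG")
  expect_equal(nrow(select_pocket(cs, 6)), 0L)
  # and a structure without the declared ligand is a structural-input error
  cs2 <- complex_structure(atoms, "XYZ")
  expect_error(select_pocket(cs2, 6), "no ligand")
})

test_that("pocket union is a checked set union with algebraic properties", {
  A <- pocket_selection("A", c(10, 11), resid = "GLY")
  B <- pocket_selection("A", c(11, 12), resid = "GLY")
  C <- pocket_selection("A", 13, resid = "GLY")
  u <- union_pockets(list(A, B))
  expect_equal(u$resno, c(10L, 11L, 12L))
  expect_equal(attr(u, "source"), "union")
  # commutative, associative, idempotent
  expect_equal(union_pockets(list(B, A))$resno, u$resno)
  expect_equal(union_pockets(list(union_pockets(list(A, B)), C))$resno,
               union_pockets(list(A, union_pockets(list(B, C))))$resno)
  expect_equal(union_pockets(rep(list(A), 9))$resno, A$resno)
  expect_error(union_pockets(list()), "non-empty")
  # mismatched numbering (same position, different residue name) is an error
  B2 <- pocket_selection("A", 11, resid = "ALA")
  expect_error(union_pockets(list(A, B2)), "mismatched residue numbering")
})

test_that("hydrogen capping counts severed bonds and incomplete termini", {
  cs <- fixture_complex("tripeptide")
  sel_all <- pocket_selection("A", 1:3, resid = "GLY")
  rc <- cap_termini(cs, sel_all)
  expect_equal(nrow(rc$caps), 2L)   # chain start + chain end only
  expect_equal(sort(rc$caps$site_atom), c("C", "N"))

  # two selected residues flanking an unselected one: 2 severed bonds plus
  # the 2 incomplete chain termini
  rc2 <- cap_termini(cs, pocket_selection("A", c(1, 3), resid = "GLY"))
  expect_equal(nrow(rc2$caps), 4L)
  expect_equal(sum(grepl("peptide", rc2$caps$replaces)), 2L)

  # complete termini (N-H and OXT present): nothing to cap
  cs3 <- fixture_complex("tripeptide", complete_termini = TRUE)
  expect_equal(nrow(cap_termini(cs3, sel_all)$caps), 0L)

  # capping adds hydrogens only and never changes the heavy-atom count
  expect_equal(sum(rc2$atoms$elem != "H"),
               sum(cs$atoms$elem != "H"
                   & paste(cs$atoms$chain, cs$atoms$resno) %in% c("A 1", "A 3")))
  expect_true(all(rc2$atoms$elem[rc2$atoms$elety == "HCP"] == "H"))
  # cap bond lengths are the standard N-H and C-H distances
  for (i in seq_len(nrow(rc2$caps))) {
    cp <- rc2$caps[i, ]
    site <- cs$atoms[cs$atoms$resno == cp$resno & cs$atoms$elety == cp$site_atom, ]
    d <- sqrt((cp$x - site$x)^2 + (cp$y - site$y)^2 + (cp$z - site$z)^2)
    expect_equal(d, if (cp$site_atom == "N") 1.01 else 1.09, tolerance = 1e-9)
  }
})

test_that("fragment annotation counts residues + metal + ligand", {
  cs <- fixture_complex("three_residue_shell")
  sel <- select_pocket(cs, 6)
  rc <- cap_termini(cs, sel)
  expect_equal(nrow(rc$fragments), nrow(sel) + 1L + 1L)  # + metal + ligand
  expect_equal(rc$fragments$type, c("residue", "residue", "metal", "ligand"))
  expect_false(any(is.na(rc$atoms$fragment)))
  # round-trip through the PDB + JSON sidecar writers
  pp <- tempfile(fileext = ".pdb")
  write_reduced(rc, pp)
  ann <- jsonlite::read_json(sub("\\.pdb$", ".json", pp))
  expect_length(ann, nrow(rc$fragments))
  expect_s3_class(bio3d::read.pdb(pp), "pdb")
})

test_that("ligand splitting partitions at the cut bond and caps both halves", {
  cs <- fixture_complex("two_ring_ligand")
  sp <- split_ligand(cs, c(4, 11))   # the inter-ring single bond
  # F1 is the sulfonamide-bearing component: ring (6 C) + S + 2 O + N = 10
  expect_equal(sp$n_heavy_f1, 10L)
  expect_equal(sp$n_heavy_f2, 6L)
  expect_equal(sp$n_heavy_f1 + sp$n_heavy_f2,
               count_heavy_atoms(cs, ligand_only = TRUE))
  # caps: F1 gains one H, F2 gains CH3 (4 atoms)
  expect_equal(nrow(sp$f1), 10L + 1L)
  expect_equal(nrow(sp$f2), 6L + 4L)
  expect_equal(sum(sp$f2$elem == "C" & sp$f2$resid == "CAP"), 1L)
  expect_equal(sum(sp$f2$elem == "H"), 3L)

  # a ring bond cannot bipartition the ligand
  expect_error(split_ligand(cs, c(1, 2)), "ring")
  # unknown serials and H-involving bonds are rejected
  expect_error(split_ligand(cs, c(4, 99)), "not in ligand")
})

test_that("a linear chain splits into the expected component sizes", {
  chain <- data.frame(serial = 1:3, elety = c("C1", "C2", "C3"), resid = "LIG",
                      chain = "A", resno = 1L, x = c(0, 1.5, 3.0), y = 0, z = 0,
                      elem = "C")
  sp <- split_ligand(chain, c(1, 2), anchor = 1)
  expect_equal(unname(count_heavy_atoms(sp)), c(1L, 2L))
})

test_that("heavy atoms are counted from structures, formulas and element lists", {
  expect_equal(count_heavy_atoms("CH4"), 1L)
  expect_equal(count_heavy_atoms("C6H6"), 6L)
  expect_equal(count_heavy_atoms("C6H7NO2S"), 10L)
  expect_equal(count_heavy_atoms(c("C", "H", "H", "O")), 2L)
  expect_error(count_heavy_atoms("C6Xx2"), "unknown element")
  expect_error(count_heavy_atoms(c("C", "QQ")), "unknown element")
  cs <- fixture_complex("two_ring_ligand")
  expect_equal(count_heavy_atoms(cs), 16L)
})

test_that("altloc conformers resolve to the highest-occupancy copy", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.60  0.00           C",
    "HETATM    3  C1  LIG A   9       1.000   0.000   0.000  1.00  0.00           C",
    "END")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  cs <- read_complex(p, "LIG")
  ca <- cs$atoms[cs$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 5.0)
})
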