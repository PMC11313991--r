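# Independent brute-force oracles shared across tests.

# canonical string key for a basic feature, used to compare enumerations as
# sets: unordered term pairs for + and *, ordered for -
bf_key <- function(f1, b1, op, f2, b2, df1, db1, dop = NA, df2 = NA, db2 = NA) {
  term <- function(f, b) paste0(f, "(", b, ")")
  pair_key <- function(fa, ba, o, fb, bb) {
    ta <- term(fa, ba); tb <- term(fb, bb)
    if (o %in% c("add", "mul")) {
      s <- sort(c(ta, tb))
      paste(s[1], o, s[2])
    } else paste(ta, o, tb)
  }
  num <- pair_key(f1, b1, op, f2, b2)
  den <- if (is.na(dop)) term(df1, db1) else pair_key(df1, db1, dop, df2, db2)
  paste(num, "//", den)
}

bf_set_keys <- function(set) {
  vapply(seq_len(nrow(set)), function(i) {
    r <- set[i, ]
    bf_key(r$nf1, r$nbp1, r$nop, r$nf2, r$nbp2,
           r$df1, r$dbp1, r$dop, r$df2, r$dbp2)
  }, "")
}

# exhaustive loop-based enumeration, deduplicated through the canonical key;
# a deliberately different code path from enumerate_basic_features()
oracle_enumerate <- function(bps, generator) {
  funs_for <- function(i) {
    if (bps$positive_definite[i]) c("x", "x2", "x3", "x4", "x5", "exp", "sqrt")
    else c("x", "x3", "x5", "exp")
  }
  nb <- nrow(bps)
  grp <- bps$group
  grp_clash <- function(bi) {
    g <- grp[bi][!is.na(grp[bi])]
    anyDuplicated(g) > 0
  }
  keys <- character(0)
  for (b1 in seq_len(nb)) for (b2 in seq_len(nb)) {
    if (b1 == b2) next
    for (f1 in funs_for(b1)) for (f2 in funs_for(b2)) for (op in c("add", "sub", "mul")) {
      if (generator == "ratio3") {
        for (b3 in seq_len(nb)) {
          if (b3 %in% c(b1, b2)) next
          if (grp_clash(c(b1, b2, b3))) next
          for (f3 in funs_for(b3))
            keys <- c(keys, bf_key(f1, bps$name[b1], op, f2, bps$name[b2],
                                   f3, bps$name[b3]))
        }
      } else {
        for (b3 in seq_len(nb)) for (b4 in seq_len(nb)) {
          if (b3 == b4) next
          u <- unique(c(b1, b2, b3, b4))
          if (!length(u) %in% 3:4) next
          if (grp_clash(u)) next
          for (f3 in funs_for(b3)) for (f4 in funs_for(b4)) for (op2 in c("add", "sub", "mul"))
            keys <- c(keys, bf_key(f1, bps$name[b1], op, f2, bps$name[b2],
                                   f3, bps$name[b3], op2, f4, bps$name[b4]))
        }
      }
    }
  }
  unique(keys)
}

# brute-force residue selection by an all-pairs distance scan
oracle_select <- function(cs, cutoff, include_h = FALSE) {
  at <- cs$atoms
  lig <- at[at$type == "ligand", ]
  res <- at[at$type == "residue", ]
  if (!include_h) {
    lig <- lig[lig$elem != "H", ]
    res <- res[res$elem != "H", ]
  }
  keys <- unique(paste(res$chain, res$resno, res$insert))
  hit <- character(0)
  for (k in keys) {
    r <- res[paste(res$chain, res$resno, res$insert) == k, ]
    found <- FALSE
    for (a in seq_len(nrow(r))) for (b in seq_len(nrow(lig))) {
      d <- sqrt((r$x[a] - lig$x[b])^2 + (r$y[a] - lig$y[b])^2 +
                  (r$z[a] - lig$z[b])^2)
      if (d <= cutoff) { found <- TRUE; break }
    }
    if (found) hit <- c(hit, k)
  }
  sort(hit)
}

# write a fixture to a temp file and read it back as a complex_structure
fixture_complex <- function(layout, ligand_resname = "LIG", ...) {
  p <- tempfile(fileext = ".pdb")
  make_pdb_fixture(layout, path = p, ...)
  read_complex(p, ligand_resname)
}
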