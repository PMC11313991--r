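HARTREE_TO_KCAL <- 627.509

#' Parse a PIEDA section from quantum-chemistry text output
#'
#' Reads the fragment catalog and the pair interaction energy decomposition
#' table from an FMO2 output stream.  The supported dialect
#' (`"gamess-fmo"`) is a fixed-column text layout modelled on GAMESS-style
#' FMO printing; see [make_pieda_fixture()] for the exact format this
#' package emits and parses.  All energies are normalized to kcal/mol at
#' parse time (1 hartree = 627.509 kcal/mol).
#'
#' @param input path to a file, a connection, or a character vector of lines.
#' @param dialect dialect identifier; only `"gamess-fmo"` is built in.
#' @return an object of class `pieda_table`: a list with
#'   \describe{
#'     \item{records}{data.frame with columns `i`, `j`, `total`, `es`, `ex`,
#'       `ct`, `disp`, `sol` (kcal/mol)}
#'     \item{fragments}{data.frame `id`, `label`,
#'       `role` in \{residue, metal, ligand\}}
#'     \item{theory, basis, dialect}{source metadata strings}
#'   }
#' @export
parse_pieda_output <- function(input, dialect = "gamess-fmo") {
  if (!identical(dialect, "gamess-fmo"))
    stop("unknown PIEDA dialect: '", dialect,
         "' (available: gamess-fmo); register a reader for other engines")
  lines <- if (is.character(input) && length(input) == 1 && file.exists(input))
    readLines(input) else if (inherits(input, "connection"))
    readLines(input) else as.character(input)

  hdr <- grep("^\\s*PIEDA INTERACTION ANALYSIS", lines)
  if (length(hdr) == 0)
    stop("no PIEDA section found (dialect gamess-fmo)")
  endl <- grep("^\\s*END PIEDA", lines)
  endl <- endl[endl > hdr[1]]
  if (length(endl) == 0)
    stop("truncated PIEDA section: no 'END PIEDA' terminator after line ", hdr[1])
  sec <- lines[hdr[1]:endl[1]]

  meta_line <- grep("^\\s*THEORY=", sec, value = TRUE)
  theory <- basis <- units <- NA_character_
  if (length(meta_line)) {
    theory <- sub(".*THEORY=\\s*(\\S+).*", "\\1", meta_line[1])
    basis <- sub(".*BASIS=\\s*(\\S+).*", "\\1", meta_line[1])
    units <- toupper(sub(".*UNITS=\\s*(\\S+).*", "\\1", meta_line[1]))
  }
  scale <- switch(units, HARTREE = HARTREE_TO_KCAL, 1)

  frag_start <- grep("^\\s*FRAGMENT LIST", sec)
  pie_start <- grep("^\\s*PAIR INTERACTION ENERGY DECOMPOSITION", sec)
  if (length(frag_start) == 0 || length(pie_start) == 0)
    stop("malformed PIEDA section: missing FRAGMENT LIST or pair table ",
         "(near line ", hdr[1], ")")

  frag_lines <- sec[(frag_start[1] + 2):(pie_start[1] - 1)]
  frag_lines <- frag_lines[nzchar(trimws(frag_lines))]
  if (length(frag_lines) == 0) stop("empty fragment listing")
  frags <- do.call(rbind, lapply(frag_lines, function(l) {
    p <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(p) < 3) stop("cannot parse fragment line: '", l, "'")
    data.frame(id = as.integer(p[1]), label = p[2], role = p[3],
               stringsAsFactors = FALSE)
  }))
  if (!all(frags$role %in% c("residue", "metal", "ligand")))
    stop("fragment role must be residue/metal/ligand")

  pie_lines <- if (pie_start[1] + 2 > length(sec) - 1) character(0)
    else sec[(pie_start[1] + 2):(length(sec) - 1)]
  pie_lines <- pie_lines[nzchar(trimws(pie_lines))]
  if (length(pie_lines) == 0)
    stop("empty PIEDA pair table (near line ", hdr[1] + pie_start[1], ")")
  recs <- do.call(rbind, lapply(seq_along(pie_lines), function(k) {
    p <- strsplit(trimws(pie_lines[k]), "\\s+")[[1]]
    if (length(p) != 8)
      stop("cannot parse PIEDA pair line ", hdr[1] + pie_start[1] + 1 + k,
           ": '", pie_lines[k], "'")
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v))
      stop("non-numeric field in PIEDA pair line ",
           hdr[1] + pie_start[1] + 1 + k)
    data.frame(i = as.integer(v[1]), j = as.integer(v[2]),
               total = v[3] * scale, es = v[4] * scale, ex = v[5] * scale,
               ct = v[6] * scale, disp = v[7] * scale, sol = v[8] * scale)
  }))
  key <- paste(pmin(recs$i, recs$j), pmax(recs$i, recs$j))
  if (anyDuplicated(key))
    stop("duplicate fragment pair(s) in PIEDA table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!all(c(recs$i, recs$j) %in% frags$id))
    stop("pair table references fragment ids missing from the catalog")
  structure(list(records = recs, fragments = frags, theory = theory,
                 basis = basis, dialect = dialect),
            class = "pieda_table")
}

#' @export
print.pieda_table <- function(x, ...) {
  cat(sprintf("<pieda_table> %d fragments, %d pairs (%s/%s)\n",
              nrow(x$fragments), nrow(x$records),
              x$theory, x$basis))
  invisible(x)
}

#' Check the PIEDA energy decomposition closure
#'
#' Every pair interaction energy must equal the sum of its five components
#' (electrostatic, exchange-repulsion, charge-transfer, dispersion,
#' solvation) within a tolerance reflecting printed-table rounding.
#'
#' @param table a `pieda_table`.
#' @param tolerance kcal/mol (default 0.05).
#' @return data.frame of violations (`i`, `j`, `total`, `component_sum`,
#'   `deviation`); zero rows when the decomposition closes.
#' @export
check_pieda_decomposition <- function(table, tolerance = 0.05) {
  stopifnot(inherits(table, "pieda_table"))
  r <- table$records
  s <- r$es + r$ex + r$ct + r$disp + r$sol
  dev <- r$total - s
  bad <- abs(dev) > tolerance
  data.frame(i = r$i[bad], j = r$j[bad], total = r$total[bad],
             component_sum = s[bad], deviation = dev[bad])
}

ligand_fragment_id <- function(table, ligand = NULL) {
  if (is.null(ligand)) {
    ids <- table$fragments$id[table$fragments$role == "ligand"]
    if (length(ids) != 1)
      stop("expected exactly one ligand fragment, found ", length(ids))
    return(ids)
  }
  if (!ligand %in% table$fragments$id)
    stop("unknown ligand fragment id: ", ligand)
  ligand
}

#' Ligand-receptor interaction energy from PIEDA
#'
#' Sums the pair interaction energies between the ligand fragment and all
#' other fragments (residues and, unless excluded via `subset`, the metal
#' ion).
#'
#' @param table a `pieda_table`.
#' @param ligand ligand fragment id; auto-detected from the fragment roles
#'   when `NULL`.
#' @param subset optional vector of partner fragment ids to restrict the
#'   sum to.
#' @return interaction energy in kcal/mol.
#' @export
ligand_interaction_energy <- function(table, ligand = NULL, subset = NULL) {
  stopifnot(inherits(table, "pieda_table"))
  lig <- ligand_fragment_id(table, ligand)
  r <- table$records
  partner <- ifelse(r$i == lig, r$j, ifelse(r$j == lig, r$i, NA_integer_))
  keep <- !is.na(partner)
  if (!is.null(subset)) keep <- keep & partner %in% subset
  sum(r$total[keep])
}

#' Construct FMO total energies
#'
#' @param e_lr,e_r,e_l total FMO energies of the complex, free receptor and
#'   free ligand.
#' @param unit `"kcal/mol"` or `"hartree"`; a single unit shared by all
#'   three values (mixed units are rejected).
#' @return an object of class `fmo_totals`.
#' @export
fmo_total_energies <- function(e_lr, e_r, e_l, unit = "kcal/mol") {
  unit <- unique(unit)
  if (length(unit) != 1)
    stop("mixed units: all three totals must share one unit")
  unit <- match.arg(unit, c("kcal/mol", "hartree"))
  vals <- c(e_lr = e_lr, e_r = e_r, e_l = e_l)
  if (any(!is.finite(vals))) stop("FMO totals must be finite")
  structure(list(e_lr = e_lr, e_r = e_r, e_l = e_l, unit = unit),
            class = "fmo_totals")
}

#' FMO binding energy
#'
#' The supermolecular FMO estimate of the binding energy: the total energy
#' of the complex minus the energies of the isolated receptor and ligand,
#' capturing polarization-destabilization and desolvation on top of the
#' pairwise interaction sum.
#'
#' @param totals an [fmo_total_energies()] object.
#' @return binding energy in kcal/mol.
#' @export
fmo_binding_energy <- function(totals) {
  stopifnot(inherits(totals, "fmo_totals"))
  d <- totals$e_lr - (totals$e_r + totals$e_l)
  if (totals$unit == "hartree") d <- d * HARTREE_TO_KCAL
  d
}

#' Normalize an energy by the ligand heavy-atom count
#'
#' Size-normalizes an interaction or binding energy to an efficiency
#' (kcal/mol per heavy atom), the common remedy for the size dependence of
#' interaction-energy magnitudes.  Used identically for the fragment
#' efficiency (interaction energy / n), the FMO ligand efficiency (binding
#' energy / n) and the hydrophobic-interaction-energy efficiency.
#'
#' @param value energy in kcal/mol.
#' @param n_heavy number of heavy (non-hydrogen) atoms, >= 1.
#' @return value / n_heavy.
#' @export
efficiency_normalize <- function(value, n_heavy) {
  if (any(!is.finite(n_heavy)) || any(n_heavy < 1))
    stop("n_heavy must be >= 1")
  value / n_heavy
}

#' Per-residue pair interaction energy profile
#'
#' One entry per residue fragment (plus the metal, labelled by role),
#' ordered by the residue number embedded in the fragment label (falling
#' back to fragment id), with the PIE total and the five decomposition
#' components.  The profile sums exactly to the ligand interaction energy
#' from the same table.
#'
#' @param table a `pieda_table`.
#' @param ligand ligand fragment id (auto-detected when `NULL`).
#' @return data.frame `fragment`, `label`, `role`, `total`, `es`, `ex`,
#'   `ct`, `disp`, `sol`.
#' @export
pie_profile <- function(table, ligand = NULL) {
  stopifnot(inherits(table, "pieda_table"))
  lig <- ligand_fragment_id(table, ligand)
  r <- table$records
  partner <- ifelse(r$i == lig, r$j, ifelse(r$j == lig, r$i, NA_integer_))
  keep <- !is.na(partner)
  out <- data.frame(fragment = partner[keep],
                    r[keep, c("total", "es", "ex", "ct", "disp", "sol")])
  m <- match(out$fragment, table$fragments$id)
  out$label <- table$fragments$label[m]
  out$role <- table$fragments$role[m]
  resno <- suppressWarnings(as.integer(gsub("\\D", "", out$label)))
  resno[is.na(resno)] <- out$fragment[is.na(resno)]
  out <- out[order(resno, out$fragment), c("fragment", "label", "role",
                                           "total", "es", "ex", "ct", "disp", "sol")]
  rownames(out) <- NULL
  out
}

#' Export per-pair PIEDA records or a profile to CSV
#'
#' @param x a `pieda_table` or a [pie_profile()] data.frame.
#' @param path output CSV file.
#' @export
write_pieda_csv <- function(x, path) {
  df <- if (inherits(x, "pieda_table")) x$records else x
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
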