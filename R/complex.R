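#' Receptor-ligand complex
#'
#' A `pf_complex` bundles one receptor structure with exactly one posed
#' small-molecule ligand. Atoms are held in tibbles with one row per atom
#' (`atom`, `element`, `res_name`, `chain`, `res_num`, `ins`, `x`, `y`,
#' `z`, `occ`, `altloc`). Ligand ring membership and formal charges, which
#' a plain PDB file cannot carry, travel as attributes and can be supplied
#' when reading.
#'
#' @param receptor,ligand Atom tibbles as described above.
#' @param metadata Free-text provenance string.
#' @param ligand_rings List of character vectors of ligand atom names, one
#'   per aromatic ring.
#' @param ligand_charges Named numeric vector of ligand formal charges
#'   (names are ligand atom names).
#' @return An object of class `pf_complex`.
#' @export
pf_complex <- function(receptor, ligand, metadata = "",
                       ligand_rings = list(), ligand_charges = numeric()) {
  receptor <- as_atom_tbl(receptor)
  ligand <- as_atom_tbl(ligand)
  x <- structure(
    list(receptor = receptor, ligand = ligand, metadata = metadata,
         ligand_rings = ligand_rings, ligand_charges = ligand_charges),
    class = "pf_complex"
  )
  validate_complex(x)
  x
}

atom_tbl_cols <- c("atom", "element", "res_name", "chain", "res_num",
                   "ins", "x", "y", "z", "occ", "altloc")

as_atom_tbl <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"ins" %in% names(df)) df$ins <- ""
  if (!"occ" %in% names(df)) df$occ <- 1
  if (!"altloc" %in% names(df)) df$altloc <- ""
  missing <- setdiff(atom_tbl_cols, names(df))
  if (length(missing) > 0) {
    abort_pf(paste0("atom table is missing column(s): ",
                    paste(missing, collapse = ", ")), "format_error")
  }
  df$res_num <- as.integer(df$res_num)
  df[atom_tbl_cols]
}

validate_complex <- function(x) {
  for (part in c("receptor", "ligand")) {
    at <- x[[part]]
    if (!all(is.finite(c(at$x, at$y, at$z)))) {
      abort_pf(paste0("non-finite coordinates in ", part), "format_error")
    }
  }
  if (nrow(x$ligand) < 1) abort_pf("complex has no ligand atoms", "format_error")
  ent <- unique(res_id(x$ligand$chain, x$ligand$res_num, x$ligand$ins))
  if (length(ent) != 1) {
    abort_pf("complex must contain exactly one ligand entity", "format_error")
  }
  invisible(x)
}

#' @export
print.pf_complex <- function(x, ...) {
  cat("<pf_complex> ", dplyr::n_distinct(res_id(x$receptor$chain, x$receptor$res_num, x$receptor$ins)),
      " receptor residues (", nrow(x$receptor), " atoms), ",
      nrow(x$ligand), " ligand atoms\n", sep = "")
  if (nzchar(x$metadata)) cat("  ", x$metadata, "\n", sep = "")
  invisible(x)
}

#' Residue identifiers of a complex's receptor
#'
#' @param complex A [pf_complex()].
#' @return Character vector of unique `chain:resnum` identifiers, in
#'   (chain, residue number, insertion code) order.
#' @export
receptor_residues <- function(complex) {
  at <- dplyr::distinct(complex$receptor, .data$chain, .data$res_num, .data$ins)
  at <- dplyr::arrange(at, .data$chain, .data$res_num, .data$ins)
  res_id(at$chain, at$res_num, at$ins)
}

#' Read a receptor-ligand complex from a PDB file
#'
#' Parses `ATOM`/`HETATM` records (via bio3d), separates the hetero entity
#' named by `ligand_selector` from the receptor, resolves alternate
#' locations (highest occupancy wins, ties broken alphabetically by altloc
#' identifier) and drops waters and all other hetero groups.
#'
#' @param pdb Path to a PDB file, or a character vector of PDB lines.
#' @param ligand_selector Either a hetero residue name (e.g. `"LIG"`) or a
#'   `"chain:resnum"` string identifying the ligand entity.
#' @param ligand_rings,ligand_charges Optional ligand annotations, see
#'   [pf_complex()].
#' @return A [pf_complex()].
#' @export
read_complex <- function(pdb, ligand_selector,
                         ligand_rings = list(), ligand_charges = numeric()) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1]) || !file.exists(pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb, "\n")), path)
    on.exit(unlink(path))
  }
  parsed <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort_pf(paste0("unparseable PDB input: ",
                                        conditionMessage(e)), "format_error")
  )
  at <- tibble::as_tibble(parsed$atom)
  atoms <- tibble::tibble(
    record = at$type,
    atom = at$elety, element = atom_element(at$elesy, at$elety),
    res_name = at$resid, chain = at$chain, res_num = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt)
  )
  atoms <- resolve_altloc(atoms)
  is_het <- atoms$record == "HETATM"
  het <- atoms[is_het & !atoms$res_name %in% c("HOH", "WAT", "DOD"), ]
  if (grepl(":", ligand_selector)) {
    parts <- strsplit(ligand_selector, ":")[[1]]
    lig <- het[het$chain == parts[1] & het$res_num == as.integer(parts[2]), ]
  } else {
    lig <- het[het$res_name == ligand_selector, ]
  }
  if (nrow(lig) == 0) {
    abort_pf(paste0("ligand selector '", ligand_selector,
                    "' matched no hetero atoms"), "selector_error")
  }
  ent <- unique(res_id(lig$chain, lig$res_num, lig$ins))
  if (length(ent) > 1) {
    abort_pf(paste0("ligand selector '", ligand_selector, "' matched ",
                    length(ent), " hetero entities: ",
                    paste(ent, collapse = ", ")), "selector_error")
  }
  pf_complex(atoms[!is_het, setdiff(names(atoms), "record")],
             lig[, setdiff(names(lig), "record")],
             metadata = paste0("read_complex(", basename(path), ")"),
             ligand_rings = ligand_rings, ligand_charges = ligand_charges)
}

atom_element <- function(elesy, elety) {
  e <- toupper(trimws(elesy))
  bad <- is.na(e) | e == ""
  # fall back to the first alphabetic character of the atom name
  e[bad] <- substr(gsub("[^A-Za-z].*", "", trimws(elety[bad])), 1, 1)
  e
}

resolve_altloc <- function(atoms) {
  atoms$.ord <- seq_len(nrow(atoms))
  out <- atoms |>
    dplyr::group_by(.data$chain, .data$res_num, .data$ins, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$altloc, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)  # keep the file's atom order
  out$.ord <- NULL
  out
}

#' Write a complex back to PDB
#'
#' Receptor atoms are emitted as `ATOM` records and ligand atoms as
#' `HETATM`, preserving the original residue numbering. Coordinates are
#' formatted to the standard three decimals, so identical complexes always
#' produce byte-identical files.
#'
#' @param complex A [pf_complex()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(complex, path) {
  fmt <- function(at, rec, serial0) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial0 + seq_len(nrow(at)),
            ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom), "",
            at$res_name, at$chain, at$res_num,
            ifelse(at$ins == "", " ", at$ins),
            at$x, at$y, at$z, at$occ, 0, at$element)
  }
  lines <- c(fmt(complex$receptor, "ATOM", 0L), "TER",
             fmt(complex$ligand, "HETATM", nrow(complex$receptor)), "END")
  writeLines(lines, path)
  invisible(path)
}
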