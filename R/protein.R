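# ProteinStructure: a classed tibble of atoms. Waters (HOH/WAT) are ordinary
# rows addressable by residue number; hydrogens are kept but all cavity and
# pharmacophore distance logic works on heavy atoms only.

#' Construct a protein structure
#'
#' A protein structure is a tibble of atoms with one row per ATOM/HETATM
#' record: `element`, coordinates `x`/`y`/`z` (Angstrom), `residue_name`
#' (3-letter code; waters are `HOH`/`WAT`), `residue_number`, `chain`,
#' `record_kind` (`ATOM` or `HETATM`) and the PDB `atom_name`.
#'
#' @param atoms A data frame with the columns listed above (missing
#'   `chain`/`record_kind`/`atom_name` are filled with defaults).
#' @return A `protein_structure` tibble.
#' @examples
#' protein_structure(tibble::tibble(
#'   element = "O", x = 0, y = 0, z = 0,
#'   residue_name = "HOH", residue_number = 770
#' ))
#' @export
protein_structure <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (!"chain" %in% names(atoms)) atoms$chain <- "A"
  if (!"record_kind" %in% names(atoms)) atoms$record_kind <- "ATOM"
  if (!"atom_name" %in% names(atoms)) atoms$atom_name <- atoms$element
  required <- c("element", "x", "y", "z", "residue_name", "residue_number")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("protein atoms lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("a protein structure needs at least one atom")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("all protein coordinates must be finite")
  }
  if (any(!nzchar(atoms$element))) abort("every atom needs an element symbol")
  atoms$element <- normalize_element(atoms$element)
  atoms <- atoms[, union(required, names(atoms))]
  class(atoms) <- c("protein_structure", class(tibble()))
  atoms
}

#' @export
print.protein_structure <- function(x, ...) {
  n_wat <- sum(x$residue_name %in% c("HOH", "WAT"))
  cat(sprintf("<protein_structure> %d atoms (%d heavy, %d water)\n",
              nrow(x), sum(is_heavy(x$element)), n_wat))
  NextMethod()
}

#' Heavy atoms of a structure
#'
#' @param protein A [protein_structure()].
#' @return The subset of atoms whose element is not hydrogen.
#' @export
heavy_atoms <- function(protein) {
  protein[is_heavy(protein$element), ]
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a [protein_structure()].
#' Waters are retained. Alternate locations are resolved by keeping, per
#' (chain, residue, atom name), the highest-occupancy altLoc; ties keep the
#' first encountered.
#'
#' @param path Path to a PDB file.
#' @return A `protein_structure` tibble.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("not parsable as PDB: ", path, " (", conditionMessage(e), ")"))
  )
  at <- tibble::as_tibble(pdb$atom)
  if (nrow(at) == 0) abort(paste0("no ATOM/HETATM records in ", path))
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altLoc: among records that carry an altLoc code, keep the
  # highest-occupancy variant of each atom site (ties: first encountered)
  at <- at %>% mutate(.ord = row_number())
  alt <- at[nzchar(at$alt), , drop = FALSE] %>%
    group_by(.data$chain, .data$resno, .data$resid, .data$elety) %>%
    arrange(desc(.data$o), .data$.ord, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  at <- bind_rows(at[!nzchar(at$alt), , drop = FALSE], alt) %>%
    arrange(.data$.ord)
  elem <- ifelse(is.na(at$elesy) | !nzchar(str_trim(at$elesy)),
                 gsub("[^A-Za-z].*$", "", str_trim(at$elety)),
                 str_trim(at$elesy))
  protein_structure(tibble(
    element = elem,
    x = at$x, y = at$y, z = at$z,
    residue_name = str_trim(at$resid),
    residue_number = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    record_kind = at$type,
    atom_name = str_trim(at$elety)
  ))
}

#' Write a PDB file
#'
#' Writes ATOM/HETATM records with fixed-width PDB columns. Coordinates are
#' written at 0.001 Angstrom precision, so read/write/read round-trips are
#' stable to that tolerance.
#'
#' @param protein A [protein_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(protein, path) {
  stopifnot(inherits(protein, "protein_structure"))
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    protein$record_kind, seq_len(nrow(protein)),
    substr(str_pad(protein$atom_name, 3, side = "right"), 1, 4), "",
    protein$residue_name, substr(protein$chain, 1, 1), protein$residue_number, "",
    protein$x, protein$y, protein$z, 1, 0, toupper(protein$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
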