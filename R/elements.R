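# Element constants shared by carving, scoring and pharmacophore logic.

# Bondi van der Waals radii (Angstrom). Unlisted elements fall back to carbon.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98
)

# Heavy-atom classes used by the pharmacophore criteria: any H-bond-capable
# heavy atom, and (for the acceptor criterion) the same set without attached H.
.HBOND_ELEMENTS <- c("N", "O", "S", "F", "Cl", "Br", "I")

#' Van der Waals radius lookup
#'
#' Bondi radii for the elements that occur in protein and drug-like ligand
#' structures. Unknown elements are assigned the carbon radius with a warning
#' suppressed (they are rare dummy atoms in synthetic fixtures).
#'
#' @param element Character vector of element symbols (case-insensitive,
#'   e.g. `"C"`, `"Cl"`).
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "N", "Cl"))
#' @export
vdw_radius <- function(element) {
  el <- normalize_element(element)
  r <- .VDW_RADII[el]
  r[is.na(r)] <- .VDW_RADII[["C"]]
  unname(r)
}

# "CL" -> "Cl", "c" -> "C"
normalize_element <- function(element) {
  el <- str_trim(element)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

is_heavy <- function(element) normalize_element(element) != "H"

# Euclidean distances from one point (length-3) to the rows of a matrix.
dist_to_points <- function(point, coords) {
  sqrt((coords[, 1] - point[1])^2 +
       (coords[, 2] - point[2])^2 +
       (coords[, 3] - point[3])^2)
}

coord_matrix <- function(df) {
  m <- cbind(df$x, df$y, df$z)
  colnames(m) <- c("x", "y", "z")
  m
}
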