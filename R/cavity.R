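# Cavity negative-image generation: FCC sphere packing around a seed point,
# carving against the protein surface, and mirror-image charge assignment.

#' Cavity generation settings
#'
#' @param filler_radius Packing-sphere radius in Angstrom (default 0.85);
#'   FCC nearest-neighbour spacing is exactly twice this.
#' @param box_radius Half-edge of the axis-aligned packing cube, Angstrom
#'   (default 20).
#' @param max_protein_distance Points farther than this from every protein
#'   heavy atom are removed (default 4.5 Angstrom).
#' @param clash_vdw_scale Scale on the protein van der Waals radii for the
#'   clash test (default 1).
#' @param hbond_distance Range within which a protein donor/acceptor flips a
#'   point's kind (default 3.5 Angstrom).
#' @param seed_point Optional Angstrom triple marking the cavity (e.g. a
#'   co-crystallized ligand centroid).
#' @return A `cavity_config` list.
#' @export
cavity_config <- function(filler_radius = 0.85, box_radius = 20,
                          max_protein_distance = 4.5, clash_vdw_scale = 1,
                          hbond_distance = 3.5, seed_point = NULL) {
  if (filler_radius <= 0 || box_radius <= 0 || hbond_distance <= 0) {
    abort("all cavity radii must be positive")
  }
  if (max_protein_distance <= filler_radius) {
    abort("max_protein_distance must exceed filler_radius")
  }
  structure(list(filler_radius = filler_radius, box_radius = box_radius,
                 max_protein_distance = max_protein_distance,
                 clash_vdw_scale = clash_vdw_scale,
                 hbond_distance = hbond_distance, seed_point = seed_point),
            class = "cavity_config")
}

#' Generate a face-centered-cubic packing lattice
#'
#' FCC sites with nearest-neighbour distance exactly `2 * filler_radius`,
#' restricted to the cube `|x - center| <= box_radius` per axis, in
#' deterministic lexicographic order of the integer lattice indices (kept as
#' columns `i`, `j`, `k`). A box smaller than one cell degenerates to the
#' single center point.
#'
#' @param center Angstrom triple, the cube center.
#' @param box_radius Half-edge of the cube (Angstrom).
#' @param filler_radius Packing-sphere radius (Angstrom).
#' @return Tibble with `x`, `y`, `z` and lattice indices `i`, `j`, `k`.
#' @examples
#' lat <- generate_fcc_lattice(c(0, 0, 0), box_radius = 3, filler_radius = 0.85)
#' min(dist(lat[, c("x", "y", "z")]))  # 1.7
#' @export
generate_fcc_lattice <- function(center, box_radius, filler_radius) {
  stopifnot(length(center) == 3, box_radius > 0, filler_radius > 0)
  half <- sqrt(2) * filler_radius        # half the conventional cube edge
  m <- floor(box_radius / half + 1e-9)
  idx <- expand.grid(k = -m:m, j = -m:m, i = -m:m)  # i slowest -> lexicographic
  idx <- idx[(idx$i + idx$j + idx$k) %% 2 == 0, c("i", "j", "k")]
  tibble(
    x = center[1] + idx$i * half,
    y = center[2] + idx$j * half,
    z = center[3] + idx$k * half,
    i = as.integer(idx$i), j = as.integer(idx$j), k = as.integer(idx$k)
  )
}

#' Carve a cavity model out of a packing lattice
#'
#' A lattice point survives when it (a) clashes with no protein heavy atom
#' (distance to every atom at least that atom's scaled van der Waals radius
#' plus the filler radius), (b) lies within `max_protein_distance` of some
#' protein heavy atom, and (c) belongs to the single lattice-contact
#' connected component containing the surviving point nearest the seed.
#' All retained points start as neutral kind `C`.
#'
#' @param lattice Point tibble from [generate_fcc_lattice()] (any tibble
#'   with `x`, `y`, `z` works; carving a carved model is a no-op).
#' @param protein A [protein_structure()].
#' @param config A [cavity_config()]; its `seed_point` (or the lattice
#'   centroid when `NULL`) selects the component.
#' @return A [nib_model()] of kind-`C` points.
#' @export
carve_cavity <- function(lattice, protein, config = cavity_config()) {
  if (nrow(lattice) == 0) abort("empty lattice")
  heavy <- heavy_atoms(protein)
  if (nrow(heavy) == 0) abort("protein has no heavy atoms")
  pts <- coord_matrix(lattice)
  pcoords <- coord_matrix(heavy)
  pradii <- vdw_radius(heavy$element) * config$clash_vdw_scale

  min_dist <- rep(Inf, nrow(pts))       # nearest heavy atom
  min_clear <- rep(Inf, nrow(pts))      # nearest approach to a vdW surface
  for (a in seq_len(nrow(pcoords))) {
    d <- dist_to_points(pcoords[a, ], pts)
    min_dist <- pmin(min_dist, d)
    min_clear <- pmin(min_clear, d - pradii[a])
  }
  no_clash <- min_clear >= config$filler_radius
  near <- min_dist <= config$max_protein_distance
  keep <- no_clash & near
  if (!any(keep)) {
    culprit <- if (!any(no_clash)) "vdW clash with the protein"
               else if (!any(near)) paste0("all points farther than ",
                                           config$max_protein_distance,
                                           " A from the protein")
               else "the clash and distance criteria jointly"
    abort(paste0("no cavity point survives carving: ", culprit))
  }
  surv <- lattice[keep, , drop = FALSE]
  seed <- config$seed_point %||% colMeans(pts)
  comp <- lattice_components(coord_matrix(surv), 2 * config$filler_radius)
  seed_idx <- which.min(dist_to_points(seed, coord_matrix(surv)))
  surv <- surv[comp == comp[seed_idx], , drop = FALSE]
  nib_model(tibble(x = surv$x, y = surv$y, z = surv$z, kind = "C"),
            filler_radius = config$filler_radius,
            provenance = "carved cavity")
}

# Connected components under nearest-neighbour lattice contact (distance ~
# spacing). Grid hashing keeps the candidate pair list linear in points.
lattice_components <- function(coords, spacing) {
  n <- nrow(coords)
  tol <- spacing * (1 + 1e-6)
  cell <- floor(coords / spacing)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  buckets <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  comp <- rep(NA_integer_, n)
  current <- 0L
  neighbor_of <- function(p) {
    cands <- integer(0)
    base <- cell[p, ]
    for (o in seq_len(nrow(offsets))) {
      k <- paste(base[1] + offsets[o, 1], base[2] + offsets[o, 2], base[3] + offsets[o, 3])
      b <- buckets[[k]]
      if (!is.null(b)) cands <- c(cands, b)
    }
    cands <- cands[cands != p]
    if (length(cands) == 0) return(integer(0))
    d <- dist_to_points(coords[p, ], coords[cands, , drop = FALSE])
    cands[d <= tol]
  }
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    current <- current + 1L
    queue <- start
    comp[start] <- current
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      nb <- neighbor_of(p)
      fresh <- nb[is.na(comp[nb])]
      comp[fresh] <- current
      queue <- c(queue, fresh)
    }
  }
  comp
}

# Fixed donor/acceptor typing on residue/atom names; no protonation
# inference. Water oxygen is both donor and acceptor.
.DONOR_ATOMS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1",
  ASN = "ND2", GLN = "NE2"
)
.ACCEPTOR_ATOMS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

polar_atom_coords <- function(protein, table) {
  heavy <- heavy_atoms(protein)
  is_water <- heavy$residue_name %in% c("HOH", "WAT")
  hit <- (heavy$atom_name %in% table$backbone & !is_water & heavy$residue_name != "PRO")
  for (res in setdiff(names(table), "backbone")) {
    hit <- hit | (heavy$residue_name == res & heavy$atom_name %in% table[[res]])
  }
  hit <- hit | (is_water & heavy$element == "O")
  coord_matrix(heavy[hit, , drop = FALSE])
}

#' Assign mirror-image charges to cavity points
#'
#' A point near a protein H-bond donor becomes a negative `O` point (it
#' mirrors the acceptor the donor would bind); a point near an acceptor
#' becomes a positive `N` point. When both partner types are in range the
#' nearer one wins, with an exact tie falling back to neutral `C`. Donor and
#' acceptor heavy atoms are identified by a fixed residue/atom-name lookup
#' (water oxygens count as both).
#'
#' @param model A carved [nib_model()].
#' @param protein The [protein_structure()] the model was carved against.
#' @param config A [cavity_config()]; `hbond_distance` bounds the search.
#' @param q Charge magnitude for the N/O kinds.
#' @return The model with kinds and charges reassigned.
#' @export
assign_point_charges <- function(model, protein, config = cavity_config(), q = 1) {
  donors <- polar_atom_coords(protein, .DONOR_ATOMS)
  acceptors <- polar_atom_coords(protein, .ACCEPTOR_ATOMS)
  pts <- coord_matrix(model)
  nearest <- function(partners) {
    if (nrow(partners) == 0) return(rep(Inf, nrow(pts)))
    d <- rep(Inf, nrow(pts))
    for (a in seq_len(nrow(partners))) {
      d <- pmin(d, dist_to_points(partners[a, ], pts))
    }
    d
  }
  d_don <- nearest(donors)
  d_acc <- nearest(acceptors)
  kind <- rep("C", nrow(pts))
  don_in <- d_don <= config$hbond_distance
  acc_in <- d_acc <= config$hbond_distance
  kind[don_in & (!acc_in | d_don < d_acc)] <- "O"
  kind[acc_in & (!don_in | d_acc < d_don)] <- "N"
  kind[don_in & acc_in & d_don == d_acc] <- "C"
  nib_model(tibble(x = model$x, y = model$y, z = model$z, kind = kind),
            filler_radius = filler_radius(model),
            provenance = attr(model, "provenance"), q = q)
}

#' Generate a cavity NIB model from a protein structure
#'
#' Convenience wrapper: FCC lattice around the seed, carve, assign charges.
#' The seed defaults to the centroid of the heavy atoms of a named HETATM
#' ligand when `seed_ligand` is given.
#'
#' @param protein A [protein_structure()].
#' @param config A [cavity_config()].
#' @param seed_ligand Optional HETATM residue name whose centroid seeds the
#'   cavity when `config$seed_point` is `NULL`.
#' @return A charged [nib_model()].
#' @export
nib_create <- function(protein, config = cavity_config(), seed_ligand = NULL) {
  seed <- config$seed_point
  if (is.null(seed) && !is.null(seed_ligand)) {
    lig <- heavy_atoms(protein)
    lig <- lig[lig$residue_name == seed_ligand & lig$record_kind == "HETATM", ]
    if (nrow(lig) == 0) abort(paste0("no HETATM residue named ", seed_ligand))
    seed <- colMeans(coord_matrix(lig))
  }
  if (is.null(seed)) abort("nib_create needs a seed point or seed ligand")
  config$seed_point <- seed
  lattice <- generate_fcc_lattice(seed, config$box_radius, config$filler_radius)
  model <- carve_cavity(lattice, protein, config)
  assign_point_charges(model, protein, config)
}
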