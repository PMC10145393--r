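# In-place (rigid) rescoring of docked poses against a NIB model:
# Gaussian shape overlap Tanimoto blended with a Hodgkin electrostatic
# similarity sampled at the model points. Poses are never moved.

#' Scoring settings
#'
#' @param w_shape Weight of the shape term in `[0, 1]`; the ESP term gets
#'   `1 - w_shape`. Default 0.5.
#' @param p Gaussian amplitude of the atom density (default 2.70), chosen so
#'   a single Gaussian reproduces a hard sphere's volume in the first-order
#'   overlap model.
#' @param esp_dielectric Dielectric constant for the pose's Coulomb field
#'   (default 1).
#' @param esp_min_distance Distance floor (Angstrom) that caps the Coulomb
#'   singularity at an observer (default 1).
#' @param point_radius Display radius of NIB points in the shape term;
#'   `NULL` (default) means twice the model's filler radius, the FCC
#'   nearest-neighbour spacing, so the point cloud forms a contiguous body.
#' @return A `score_config` list.
#' @export
score_config <- function(w_shape = 0.5, p = 2.70, esp_dielectric = 1,
                         esp_min_distance = 1.0, point_radius = NULL) {
  if (w_shape < 0 || w_shape > 1) abort("w_shape must lie in [0, 1]")
  if (p <= 1) abort("gaussian amplitude p must exceed 1")
  structure(list(w_shape = w_shape, w_esp = 1 - w_shape, p = p,
                 esp_dielectric = esp_dielectric,
                 esp_min_distance = esp_min_distance,
                 point_radius = point_radius),
            class = "score_config")
}

# Gaussian decay constants: alpha_i = kappa / R_i^2 with
# kappa = pi * (3 p / (4 pi))^(2/3), so each atom Gaussian integrates to the
# volume of its hard sphere.
gaussian_alpha <- function(radius, p) {
  kappa <- pi * (3 * p / (4 * pi))^(2 / 3)
  kappa / radius^2
}

# Total pairwise first-order overlap volume between two Gaussian bodies.
gaussian_overlap <- function(ca, ra, cb, rb, p) {
  aa <- gaussian_alpha(ra, p)
  ab <- gaussian_alpha(rb, p)
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
  d2[d2 < 0] <- 0
  s <- outer(aa, ab, "+")
  prod_ <- outer(aa, ab, "*")
  sum(p^2 * (pi / s)^1.5 * exp(-prod_ * d2 / s))
}

#' Gaussian shape Tanimoto between two atom sets
#'
#' First-order Gaussian-overlap model: each body is a sum of atom Gaussians
#' `g_i(r) = p exp(-alpha_i |r - r_i|^2)` and the similarity is
#' `T = O_AB / (O_AA + O_BB - O_AB)` over the analytic pairwise overlap
#' volumes. Symmetric, rigid-motion invariant, 1 for identical sets.
#'
#' @param a,b Data frames with `x`, `y`, `z` and `radius` columns (Angstrom).
#' @param p Gaussian amplitude (see [score_config()]).
#' @return Similarity in `[0, 1]`.
#' @examples
#' atoms <- tibble::tibble(x = 0:1, y = 0, z = 0, radius = 1.7)
#' shape_tanimoto(atoms, atoms)  # 1
#' @export
shape_tanimoto <- function(a, b, p = 2.70) {
  if (nrow(a) == 0 || nrow(b) == 0) abort("shape_tanimoto needs non-empty atom sets")
  if (any(a$radius <= 0) || any(b$radius <= 0)) abort("radii must be positive")
  ca <- coord_matrix(a); cb <- coord_matrix(b)
  oab <- gaussian_overlap(ca, a$radius, cb, b$radius, p)
  oaa <- gaussian_overlap(ca, a$radius, ca, a$radius, p)
  obb <- gaussian_overlap(cb, b$radius, cb, b$radius, p)
  oab / (oaa + obb - oab)
}

# Pose Coulomb field sampled at the model points (distance-floored).
pose_field_at_points <- function(atoms, pts, config) {
  field <- rep(0, nrow(pts))
  if (all(atoms$charge == 0)) return(field)
  for (a in seq_len(nrow(atoms))) {
    if (atoms$charge[a] == 0) next
    d <- pmax(dist_to_points(c(atoms$x[a], atoms$y[a], atoms$z[a]), pts),
              config$esp_min_distance)
    field <- field + atoms$charge[a] / (config$esp_dielectric * d)
  }
  field
}

#' Hodgkin electrostatic similarity of a pose to a NIB model
#'
#' The observers are the model's own point centers; the reference field is
#' the point charges themselves (the model *is* the target field), and the
#' pose field is a distance-floored Coulomb sum over its partial charges:
#' `H = 2 sum(E_pose E_model) / (sum(E_pose^2) + sum(E_model^2))`, which is
#' exactly +1/-1 when the two fields are identical/negated and defined as 0
#' when both vanish.
#'
#' @param pose A [pose()].
#' @param model A [nib_model()].
#' @param config A [score_config()].
#' @return Similarity in `[-1, 1]`.
#' @export
esp_hodgkin <- function(pose, model, config = score_config()) {
  if (nrow(model) == 0) abort("esp_hodgkin needs a non-empty model")
  pts <- coord_matrix(model)
  e_pose <- pose_field_at_points(pose_heavy_atoms(pose), pts, config)
  e_model <- model$charge
  denom <- sum(e_pose^2) + sum(e_model^2)
  if (denom == 0) return(0)
  2 * sum(e_pose * e_model) / denom
}

#' Combined shape/ESP score of a pose against a NIB model
#'
#' `w_shape * shape_tanimoto + (1 - w_shape) * esp_hodgkin`, computed on the
#' pose's heavy atoms (element van der Waals radii) against the model points
#' (display radius from the config). Rigid: the pose is scored where it
#' stands.
#'
#' @inheritParams esp_hodgkin
#' @return A scalar score.
#' @export
nib_score <- function(pose, model, config = score_config()) {
  heavy <- pose_heavy_atoms(pose)
  if (nrow(heavy) == 0) abort("pose has no heavy atoms")
  pr <- config$point_radius %||% (2 * filler_radius(model))
  t_shape <- shape_tanimoto(
    tibble(x = heavy$x, y = heavy$y, z = heavy$z, radius = vdw_radius(heavy$element)),
    tibble(x = model$x, y = model$y, z = model$z, radius = pr),
    p = config$p
  )
  if (config$w_shape == 1) return(t_shape)
  h <- esp_hodgkin(pose, model, config)
  config$w_shape * t_shape + config$w_esp * h
}

#' Rescore a set of docked poses against a NIB model
#'
#' One screen record per pose, ordered by score (descending; ties by
#' compound then entry/pose ID). Compound-level decisions use the
#' best-scoring duplicate: pipe the result into [collapse_best_pose()] or
#' set `collapse = TRUE`.
#'
#' @param poses List of [pose()] objects.
#' @param model A [nib_model()].
#' @param config A [score_config()].
#' @param actives Optional character vector of active compound IDs used to
#'   label the records (everything else becomes `"decoy"`); `NULL` leaves
#'   labels `"unknown"`.
#' @param collapse If `TRUE`, return the per-compound best-pose table
#'   instead of the per-pose table.
#' @return A screen-record tibble.
#' @export
rescore_poses <- function(poses, model, config = score_config(),
                          actives = NULL, collapse = FALSE) {
  if (length(poses) == 0) abort("no poses to rescore")
  records <- list_rbind(map(poses, function(p) {
    tibble(compound_id = p$compound_id, entry_id = p$entry_id,
           pose_id = p$pose_id, score = nib_score(p, model, config),
           label = "unknown")
  }))
  if (!is.null(actives)) records <- label_records(records, actives)
  records <- screen_records(records) %>%
    arrange(desc(.data$score), .data$compound_id, .data$entry_id, .data$pose_id)
  if (collapse) collapse_best_pose(records) else records
}
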