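# Anchored pharmacophore-point filtering of docked poses: each region is one
# or more spheres around residue-derived anchors plus an atom-class
# criterion, combined by a boolean pass-logic expression, with an extra
# proximity conjunct.

.PHA_CRITERIA <- c("hbond_heavy", "aromatic_atom", "acceptor_heavy")

#' Construct a pharmacophore model
#'
#' @param points Tibble with `region_id` (integer), anchor coordinates
#'   `x`/`y`/`z` (Angstrom), `radius` (Angstrom), `criterion` (one of
#'   `"hbond_heavy"`, `"aromatic_atom"`, `"acceptor_heavy"`) and a free-text
#'   `anchor_label`. A region with several points is satisfied when any one
#'   of them is.
#' @param pass_logic Boolean expression over `r1`..`r5` region outcomes,
#'   e.g. `"(r1 & r2 & r3 & r4) | (r2 & r3 & r4 & r5)"`.
#' @param proximity Optional list with `anchors` (matrix of anchor
#'   coordinates, one row each), `radius` and `labels`; a pose must place a
#'   heavy atom within `radius` of at least one anchor, as an additional
#'   conjunct to `pass_logic`.
#' @return A `pha_model`.
#' @export
pha_model <- function(points, pass_logic, proximity = NULL) {
  points <- as_tibble(points)
  if (any(points$radius <= 0)) abort("pharmacophore radii must be positive")
  if (!all(points$criterion %in% .PHA_CRITERIA)) {
    abort(paste0("criteria must be one of: ", paste(.PHA_CRITERIA, collapse = ", ")))
  }
  vars <- all.vars(parse(text = pass_logic))
  known <- paste0("r", sort(unique(points$region_id)))
  if (!all(vars %in% known)) {
    abort(paste0("pass_logic references undefined region(s): ",
                 paste(setdiff(vars, known), collapse = ", ")))
  }
  structure(list(points = points, pass_logic = pass_logic,
                 proximity = proximity),
            class = "pha_model")
}

#' @export
print.pha_model <- function(x, ...) {
  cat(sprintf("<pha_model> %d points across %d regions; logic: %s\n",
              nrow(x$points), length(unique(x$points$region_id)), x$pass_logic))
  invisible(x)
}

# Anchor convention (documented, exportable): His = ring-N centroid,
# Tyr = hydroxyl O, Phe = ring centroid, Leu = CD1/CD2 midpoint,
# Arg = guanidinium C, water = O. Residues present without the expected
# side-chain atoms fall back to their heavy-atom centroid.
.ANCHOR_ATOMS <- list(
  HIS = c("ND1", "NE2"), TYR = "OH",
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  LEU = c("CD1", "CD2"), ARG = "CZ", HOH = "O", WAT = "O"
)

residue_anchor <- function(protein, residue_number) {
  res <- heavy_atoms(protein)
  res <- res[res$residue_number == residue_number, , drop = FALSE]
  if (nrow(res) == 0) return(NULL)
  wanted <- .ANCHOR_ATOMS[[res$residue_name[1]]]
  sel <- res[res$atom_name %in% wanted, , drop = FALSE]
  if (nrow(sel) == 0) sel <- res
  list(coord = colMeans(coord_matrix(sel)),
       label = paste0(res$residue_name[1], residue_number))
}

#' Build the default five-region RORgamma-t pharmacophore model
#'
#' Encodes the activity hotspots of the RORgamma-t ligand-binding domain:
#' region 1, H-bond-capable heavy atoms at His479/Tyr502 (radius 4.0 A);
#' region 2, aromatic atoms at Leu324/Phe388 (4.5 A); region 3, aromatic
#' atoms at Phe378 (5.2 A); region 4, H-bond-capable heavy atoms at
#' His323 or the structural water (4.0 A); region 5, an H-bond acceptor at
#' Arg367 (4.0 A). A pose passes with regions 1-4 or with regions 2-5, and
#' must additionally place a heavy atom within 4.0 A of His479 or Tyr502.
#'
#' @param protein A [protein_structure()] containing the named residues and
#'   the structural water.
#' @param water_residue Residue number of the structural water (default 770).
#' @return A [pha_model()] with 8 anchored spheres across 5 regions (two
#'   each in regions 1, 2 and 4).
#' @export
build_default_rorgt_model <- function(protein, water_residue = 770) {
  spec <- tibble(
    region_id = c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L),
    residue = c(479, 502, 324, 388, 378, 323, water_residue, 367),
    radius = c(4.0, 4.0, 4.5, 4.5, 5.2, 4.0, 4.0, 4.0),
    criterion = c("hbond_heavy", "hbond_heavy", "aromatic_atom", "aromatic_atom",
                  "aromatic_atom", "hbond_heavy", "hbond_heavy", "acceptor_heavy")
  )
  anchors <- map(spec$residue, ~ residue_anchor(protein, .x))
  missing_res <- spec$residue[map_lgl(anchors, is.null)]
  if (length(missing_res) > 0) {
    abort(paste0("protein lacks pharmacophore anchor residue(s)/water: ",
                 paste(unique(missing_res), collapse = ", ")))
  }
  # one sphere per row; multi-anchor regions (1, 2, 4) are OR-combined
  pts <- tibble(
    region_id = spec$region_id,
    x = map_dbl(anchors, ~ .x$coord[1]),
    y = map_dbl(anchors, ~ .x$coord[2]),
    z = map_dbl(anchors, ~ .x$coord[3]),
    radius = spec$radius,
    criterion = spec$criterion,
    anchor_label = map_chr(anchors, "label")
  )
  prox <- list(anchors = coord_matrix(pts[pts$region_id == 1L, ]),
               radius = 4.0,
               labels = pts$anchor_label[pts$region_id == 1L])
  pha_model(pts,
            pass_logic = "(r1 & r2 & r3 & r4) | (r2 & r3 & r4 & r5)",
            proximity = prox)
}

# Per-atom feature flags used by the criteria.
pose_atom_features <- function(pose) {
  at <- pose$atoms
  hb <- normalize_element(at$element) %in% .HBOND_ELEMENTS
  has_h <- rep(FALSE, nrow(at))
  b <- pose$bonds
  if (nrow(b) > 0) {
    h_atoms <- which(!is_heavy(at$element))
    has_h[b$i[b$j %in% h_atoms]] <- TRUE
    has_h[b$j[b$i %in% h_atoms]] <- TRUE
  }
  tibble(heavy = is_heavy(at$element), hbond = hb,
         acceptor = hb & !has_h, aromatic = at$aromatic)
}

#' Is a region satisfied by a pose?
#'
#' A region is satisfied when any of its points contains a qualifying atom:
#' `hbond_heavy` needs an N/O/S/F/Cl/Br/I atom within the radius;
#' `aromatic_atom` an aromatic-flagged atom; `acceptor_heavy` an
#' N/O/S/F/Cl/Br/I atom with no attached hydrogen.
#'
#' @param pose A [pose()] in the same frame as the anchors.
#' @param points_of_region Rows of a [pha_model()]'s `points` for one region.
#' @return Logical flag.
#' @export
region_satisfied <- function(pose, points_of_region) {
  feats <- pose_atom_features(pose)
  at <- pose$atoms
  for (r in seq_len(nrow(points_of_region))) {
    pt <- points_of_region[r, ]
    eligible <- switch(pt$criterion,
                       hbond_heavy = feats$hbond,
                       aromatic_atom = feats$aromatic & feats$heavy,
                       acceptor_heavy = feats$acceptor)
    if (!any(eligible)) next
    d <- dist_to_points(c(pt$x, pt$y, pt$z),
                        coord_matrix(at[eligible, , drop = FALSE]))
    if (any(d <= pt$radius)) return(TRUE)
  }
  FALSE
}

#' Filter poses through a pharmacophore model
#'
#' Evaluates each region's criterion per pose, the pass-logic expression,
#' and the proximity rule; a pose passes when logic and proximity both hold.
#' A compound passes when any of its poses does (see
#' [pha_compound_verdicts()]).
#'
#' @param poses List of [pose()] objects.
#' @param model A [pha_model()].
#' @return Tibble with one row per pose: IDs, one `r<k>` column per region,
#'   `proximity` and `pass`.
#' @export
pha_filter <- function(poses, model) {
  regions <- sort(unique(model$points$region_id))
  rows <- map(poses, function(p) {
    sat <- setNames(
      map_lgl(regions, ~ region_satisfied(p, model$points[model$points$region_id == .x, ])),
      paste0("r", regions))
    prox <- TRUE
    if (!is.null(model$proximity)) {
      heavy <- pose_heavy_atoms(p)
      prox <- any(map_lgl(seq_len(nrow(model$proximity$anchors)), function(a) {
        any(dist_to_points(model$proximity$anchors[a, ], coord_matrix(heavy)) <=
              model$proximity$radius)
      }))
    }
    logic <- isTRUE(eval(parse(text = model$pass_logic), envir = as.list(sat)))
    as_tibble(c(list(compound_id = p$compound_id, entry_id = p$entry_id,
                     pose_id = p$pose_id), as.list(sat),
                list(proximity = prox, pass = logic && prox)))
  })
  list_rbind(rows)
}

#' Collapse pose verdicts to compound verdicts
#'
#' @param verdicts Output of [pha_filter()].
#' @return Tibble with `compound_id` and `pass` (any pose passing).
#' @export
pha_compound_verdicts <- function(verdicts) {
  verdicts %>%
    group_by(.data$compound_id) %>%
    summarise(pass = any(.data$pass), .groups = "drop")
}
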