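# Deterministic synthetic fixtures: a box-shaped protein pocket with
# pharmacophore anchor residues, plug-shaped active poses vs displaced
# decoys, and Normal score sets. Everything the screening protocol needs,
# generated in code.

#' Fixture generation settings
#'
#' @param seed Integer seed; the same spec always produces bit-identical
#'   fixtures.
#' @param pocket_dims Angstrom triple, inner pocket dimensions (min 4 per
#'   axis).
#' @param n_actives,n_decoys Compound counts for pose/score sets.
#' @param active_fit Geometric complementarity dial in `[0, 1]`: actives
#'   are jittered by `(1 - active_fit) * 1` Angstrom.
#' @param score_separation Standardized effect size between active and
#'   decoy score distributions in [make_score_set()].
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, pocket_dims = c(8, 8, 8), n_actives = 20,
                         n_decoys = 40, active_fit = 0.9,
                         score_separation = 2) {
  if (any(pocket_dims < 4)) abort("pocket_dims must be at least 4 Angstrom per axis")
  structure(list(seed = as.integer(seed), pocket_dims = pocket_dims,
                 n_actives = n_actives, n_decoys = n_decoys,
                 active_fit = active_fit, score_separation = score_separation),
            class = "fixture_spec")
}

#' Synthetic box pocket
#'
#' Dummy heavy atoms tile five faces of a rectangular pocket (open top) at
#' 1.5 Angstrom spacing. The walls carry one H-bond donor (a lysine
#' ammonium N) and one acceptor (a backbone carbonyl O) so charge
#' assignment is exercised, and the eight pharmacophore anchor residues
#' (His479, Tyr502, Leu324, Phe388, Phe378, His323, Arg367 and the
#' structural water) sit just behind the walls so the default
#' pharmacophore model can be built against the fixture. Deterministic; no
#' randomness involved.
#'
#' @param spec A [fixture_spec()].
#' @return List with `protein` (a [protein_structure()]) and `seed_point`
#'   (the pocket centroid).
#' @export
make_box_pocket <- function(spec = fixture_spec()) {
  d <- spec$pocket_dims / 2
  dz <- spec$pocket_dims[3]
  off <- 0.5                      # wall planes sit this far outside the interior
  step <- 1.5
  gx <- seq(-d[1] - off, d[1] + off, by = step)
  gy <- seq(-d[2] - off, d[2] + off, by = step)
  gz <- seq(-off, dz, by = step)
  wall <- bind_rows(
    tidyr::expand_grid(x = gx, y = gy) %>% mutate(z = -off),        # floor
    tidyr::expand_grid(y = gy, z = gz) %>% mutate(x = -d[1] - off), # -x
    tidyr::expand_grid(y = gy, z = gz) %>% mutate(x = d[1] + off),  # +x
    tidyr::expand_grid(x = gx, z = gz) %>% mutate(y = -d[2] - off), # -y
    tidyr::expand_grid(x = gx, z = gz) %>% mutate(y = d[2] + off)   # +y
  ) %>% distinct(.data$x, .data$y, .data$z)
  atoms <- tibble(element = "C", x = wall$x, y = wall$y, z = wall$z,
                  residue_name = "DUM", residue_number = 1L,
                  chain = "A", record_kind = "ATOM", atom_name = "C")
  # polar wall atoms driving mirror-image charge assignment; they protrude
  # slightly into the pocket so carved points fall inside H-bond range
  polar <- tibble(
    element = c("O", "N"),
    x = c(0, 0), y = c(-d[2] - off + 1.2, d[2] + off - 1.2), z = c(dz / 2, dz / 2),
    residue_name = c("GLY", "LYS"), residue_number = c(2L, 3L),
    chain = "A", record_kind = "ATOM", atom_name = c("O", "NZ")
  )
  behind <- 1.0                   # anchors sit this far behind the wall plane
  ring <- function(cx, cy, cz, plane = "xz") {
    ang <- seq(0, 2 * pi, length.out = 7)[1:6]
    if (plane == "xz") tibble(x = cx + 1.4 * cos(ang), y = cy, z = cz + 1.4 * sin(ang))
    else tibble(x = cx, y = cy + 1.4 * cos(ang), z = cz + 1.4 * sin(ang))
  }
  anchor_atoms <- bind_rows(
    tibble(element = "N", x = -d[1] - off - behind, y = c(-0.5, 0.5), z = 0.7 * dz,
           residue_name = "HIS", residue_number = 479L, atom_name = c("ND1", "NE2")),
    tibble(element = "O", x = d[1] + off + behind, y = 0, z = 0.7 * dz,
           residue_name = "TYR", residue_number = 502L, atom_name = "OH"),
    tibble(element = "C", x = c(-0.5, 0.5), y = -d[2] - off - behind, z = 0.6 * dz,
           residue_name = "LEU", residue_number = 324L, atom_name = c("CD1", "CD2")),
    ring(0, d[2] + off + behind, 0.5 * dz, "xz") %>%
      mutate(element = "C", residue_name = "PHE", residue_number = 388L,
             atom_name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    ring(0, 0, -off - behind - 1.4, "yz") %>%
      mutate(element = "C", residue_name = "PHE", residue_number = 378L,
             atom_name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    tibble(element = "N", x = d[1] + off + behind, y = c(-0.5, 0.5), z = 0.2 * dz,
           residue_name = "HIS", residue_number = 323L, atom_name = c("ND1", "NE2")),
    tibble(element = "C", x = -d[1] - off - behind, y = 0, z = 0.2 * dz,
           residue_name = "ARG", residue_number = 367L, atom_name = "CZ")
  ) %>% mutate(chain = "A", record_kind = "ATOM")
  water <- tibble(element = "O", x = d[1] + off + behind, y = 1.5, z = 0.2 * dz,
                  residue_name = "HOH", residue_number = 770L,
                  chain = "A", record_kind = "HETATM", atom_name = "O")
  protein <- protein_structure(bind_rows(atoms, polar, anchor_atoms, water))
  list(protein = protein, seed_point = c(0, 0, dz / 2))
}

# interior plug grid shared by actives and decoys (centered in the pocket)
plug_grid <- function(dims) {
  d <- dims / 2
  axis <- function(lo, hi, by = 2) {
    v <- seq(lo, hi, by = by)
    v + (hi - v[length(v)]) / 2
  }
  g <- tidyr::expand_grid(
    x = axis(-d[1] + 1.2, d[1] - 1.2),
    y = axis(-d[2] + 1.2, d[2] - 1.2),
    z = axis(1.2, dims[3] - 1.2)
  )
  as.matrix(g)
}

#' Synthetic labelled pose set for a box pocket
#'
#' Actives are plug-shaped atom clusters filling the pocket (jittered by
#' `(1 - active_fit)` Angstrom) with partial charges complementary to the
#' wall polarity and with H-bonding / aromatic atoms planted next to each
#' pharmacophore anchor; decoys are the same-size clusters displaced and
#' rotated out of the pocket. Each pose carries `ALOGP` and `MMGBSA`
#' properties so funnel filters are exercisable. Pure function of the spec.
#'
#' @param spec A [fixture_spec()].
#' @param pocket Output of [make_box_pocket()] for the same spec.
#' @return List with `poses` (actives then decoys) and `actives` (IDs).
#' @export
make_pose_set <- function(spec = fixture_spec(), pocket = make_box_pocket(spec)) {
  base <- plug_grid(spec$pocket_dims)
  pha <- build_default_rorgt_model(pocket$protein)
  jit <- (1 - spec$active_fit) * 1
  d <- spec$pocket_dims / 2

  decorate <- function(coords) {
    at <- tibble(element = "C", x = coords[, 1], y = coords[, 2], z = coords[, 3],
                 charge = 0, aromatic = FALSE)
    # complementary charges near the polar walls (acceptor O at -y, donor N at +y)
    at$charge[at$y < -d[2] + 2.2] <- 0.5
    at$charge[at$y > d[2] - 2.2] <- -0.5
    # plant criterion atoms nearest each anchor
    for (r in seq_len(nrow(pha$points))) {
      pt <- pha$points[r, ]
      nearest <- which.min(dist_to_points(c(pt$x, pt$y, pt$z), coord_matrix(at)))
      if (pt$criterion == "aromatic_atom") {
        at$aromatic[nearest] <- TRUE
      } else {
        at$element[nearest] <- if (pt$criterion == "acceptor_heavy") "O" else "N"
      }
    }
    at
  }

  rot_z <- function(coords, theta) {
    cbind(coords[, 1] * cos(theta) - coords[, 2] * sin(theta),
          coords[, 1] * sin(theta) + coords[, 2] * cos(theta),
          coords[, 3])
  }

  withr::with_seed(spec$seed, {
    poses <- list()
    ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
    act_ids <- ids("ACT", spec$n_actives)
    dec_ids <- ids("DEC", spec$n_decoys)
    for (k in seq_len(spec$n_actives)) {
      coords <- base + matrix(runif(length(base), -jit, jit), nrow(base))
      at <- decorate(coords)
      poses[[length(poses) + 1]] <- pose(
        act_ids[k], at,
        properties = c(ALOGP = sprintf("%.2f", runif(1, 1, 5)),
                       MMGBSA = sprintf("%.2f", runif(1, -120, -100))))
    }
    for (k in seq_len(spec$n_decoys)) {
      shift <- c(spec$pocket_dims[1] + 6 + runif(1, 0, 2),
                 runif(1, -2, 2), spec$pocket_dims[3] + runif(1, 0, 2))
      coords <- sweep(rot_z(base, runif(1, 0, 2 * pi)), 2, shift, `+`)
      at <- tibble(element = "C", x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   charge = 0, aromatic = FALSE)
      poses[[length(poses) + 1]] <- pose(
        dec_ids[k], at,
        properties = c(ALOGP = sprintf("%.2f", runif(1, 1, 7)),
                       MMGBSA = sprintf("%.2f", runif(1, -110, -80))))
    }
    list(poses = poses, actives = act_ids)
  })
}

#' Synthetic score set
#'
#' Active scores are Normal(mean + separation, 1), decoys Normal(mean, 1),
#' which makes the expected AUC `pnorm(separation / sqrt(2))` -- the
#' closed form the test suite checks against.
#'
#' @param spec A [fixture_spec()]; `score_separation` is the effect size.
#' @param mean Decoy score mean.
#' @return A labelled screen-record tibble.
#' @export
make_score_set <- function(spec = fixture_spec(), mean = 0) {
  withr::with_seed(spec$seed, {
    screen_records(tibble(
      compound_id = c(sprintf("ACT%04d", seq_len(spec$n_actives)),
                      sprintf("DEC%04d", seq_len(spec$n_decoys))),
      score = c(rnorm(spec$n_actives, mean + spec$score_separation),
                rnorm(spec$n_decoys, mean)),
      label = rep(c("active", "decoy"), c(spec$n_actives, spec$n_decoys))
    ))
  })
}
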