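# Five-region pharmacophore model construction, region criteria, pass
# logic, and the brute-force verdict oracle.

pha_fixture <- function() {
  fx <- fixture_pocket()
  list(protein = fx$pocket$protein,
       model = build_default_rorgt_model(fx$pocket$protein))
}

# pose with one atom planted at a given offset from a model point's anchor
planted_pose <- function(model, region, offset, element = "C", aromatic = FALSE,
                         extra = NULL, id = "plant") {
  pt <- model$points[model$points$region_id == region, ][1, ]
  atoms <- tibble::tibble(element = element,
                          x = pt$x + offset, y = pt$y, z = pt$z,
                          aromatic = aromatic)
  if (!is.null(extra)) atoms <- dplyr::bind_rows(atoms, extra)
  pose(id, atoms)
}

test_that("the default model has the published radii, criteria and logic", {
  m <- pha_fixture()$model
  expect_equal(nrow(m$points), 8)
  expect_equal(sort(unique(m$points$region_id)), 1:5)
  radii <- tapply(m$points$radius, m$points$region_id, unique)
  expect_equal(as.numeric(radii), c(4.0, 4.5, 5.2, 4.0, 4.0))
  crit <- tapply(m$points$criterion, m$points$region_id, unique)
  expect_equal(as.character(crit), c("hbond_heavy", "aromatic_atom", "aromatic_atom",
                                     "hbond_heavy", "acceptor_heavy"))
  expect_match(m$pass_logic, "r1 & r2 & r3 & r4")
  expect_match(m$pass_logic, "r2 & r3 & r4 & r5")
  expect_equal(m$proximity$radius, 4.0)
  expect_setequal(m$proximity$labels, c("HIS479", "TYR502"))
})

test_that("a missing anchor residue or water fails construction by name", {
  fx <- fixture_pocket()
  prot <- fx$pocket$protein
  no_water <- protein_structure(prot[prot$residue_number != 770, ])
  expect_error(build_default_rorgt_model(no_water), "770")
})

test_that("region criteria respect element class, aromaticity and the strict radius", {
  m <- pha_fixture()$model
  r1 <- m$points[m$points$region_id == 1, ]
  # N atom 3.9 A from the His479 anchor satisfies region 1; 4.1 A does not
  expect_true(region_satisfied(planted_pose(m, 1, 3.9, element = "N"), r1))
  expect_false(region_satisfied(planted_pose(m, 1, 4.1, element = "N"), r1))
  # a carbon at 3.9 A does not qualify as an H-bonding heavy atom
  expect_false(region_satisfied(planted_pose(m, 1, 3.9, element = "C"), r1))

  # aromatic criterion: flagged atom within 4.5, non-flagged never
  r2 <- m$points[m$points$region_id == 2, ]
  expect_true(region_satisfied(planted_pose(m, 2, 4.4, aromatic = TRUE), r2))
  expect_false(region_satisfied(planted_pose(m, 2, 4.4, aromatic = FALSE), r2))
  # 4.6 A from one region-2 anchor: only satisfied if within range of the other
  p46 <- planted_pose(m, 2, 4.6, aromatic = TRUE)
  d_other <- sqrt(sum((c(p46$atoms$x, p46$atoms$y, p46$atoms$z) -
                       unlist(r2[2, c("x", "y", "z")]))^2))
  expect_equal(region_satisfied(p46, r2), d_other <= 4.5)

  # acceptor criterion rejects an O that carries an explicit hydrogen
  r5 <- m$points[m$points$region_id == 5, ]
  pt5 <- r5[1, ]
  oh <- pose("oh", tibble::tibble(element = c("O", "H"),
                                  x = pt5$x + c(3, 3.5), y = pt5$y, z = pt5$z),
             bonds = tibble::tibble(i = 1L, j = 2L, order = 1L))
  expect_false(region_satisfied(oh, r5))
  o_bare <- pose("o", tibble::tibble(element = "O", x = pt5$x + 3, y = pt5$y, z = pt5$z))
  expect_true(region_satisfied(o_bare, r5))
})

test_that("a carbon-only pose satisfies none of the polar regions", {
  m <- pha_fixture()$model
  p <- pose("cc", tibble::tibble(element = "C", x = 0, y = 0, z = 4))
  for (region in c(1, 4, 5)) {
    expect_false(region_satisfied(p, m$points[m$points$region_id == region, ]))
  }
})

test_that("pass logic: either four-region clause passes, but only with proximity", {
  fx <- fixture_pocket()
  m <- fx$model <- build_default_rorgt_model(fx$pocket$protein)
  # fixture actives satisfy all regions and proximity
  v_act <- pha_filter(fx$poses$poses[1:3], m)
  expect_true(all(v_act$pass))
  expect_true(all(v_act$r1 & v_act$r2 & v_act$r3 & v_act$r4))
  # displaced decoys fail
  dec_idx <- which(!vapply(fx$poses$poses, function(p) p$compound_id, "") %in%
                     fx$poses$actives)[1:3]
  v_dec <- pha_filter(fx$poses$poses[dec_idx], m)
  expect_false(any(v_dec$pass))

  # regions 2,3,4 only -> fails both clauses even with proximity satisfied
  act <- fx$poses$poses[[1]]
  at <- act$atoms
  at$element[at$element %in% c("N", "O")] <- "C"  # kill regions 1, 4, 5
  p234 <- pose("p234", at)
  v <- pha_filter(list(p234), m)
  expect_true(v$r2 && v$r3)
  expect_false(v$r1 || v$r5)
  expect_false(v$pass)
})

test_that("verdicts match a brute-force distance-check oracle on a synthetic set", {
  fx <- fixture_pocket()
  m <- build_default_rorgt_model(fx$pocket$protein)
  poses <- fx$poses$poses
  oracle_verdict <- function(p) {
    feats <- list(
      hbond_heavy = p$atoms$element %in% c("N", "O", "S", "F", "Cl", "Br", "I"),
      aromatic_atom = p$atoms$aromatic & p$atoms$element != "H",
      acceptor_heavy = p$atoms$element %in% c("N", "O", "S", "F", "Cl", "Br", "I")
      # fixture poses are bond-less, so acceptor == hbond class here
    )
    sat <- vapply(1:5, function(rg) {
      pts <- m$points[m$points$region_id == rg, ]
      any(vapply(seq_len(nrow(pts)), function(r) {
        el <- feats[[pts$criterion[r]]]
        if (!any(el)) return(FALSE)
        d <- sqrt((p$atoms$x[el] - pts$x[r])^2 + (p$atoms$y[el] - pts$y[r])^2 +
                    (p$atoms$z[el] - pts$z[r])^2)
        any(d <= pts$radius[r])
      }, logical(1)))
    }, logical(1))
    heavy <- p$atoms[p$atoms$element != "H", ]
    prox <- any(vapply(seq_len(nrow(m$proximity$anchors)), function(a) {
      any(sqrt((heavy$x - m$proximity$anchors[a, 1])^2 +
                 (heavy$y - m$proximity$anchors[a, 2])^2 +
                 (heavy$z - m$proximity$anchors[a, 3])^2) <= m$proximity$radius)
    }, logical(1)))
    ((sat[1] && sat[2] && sat[3] && sat[4]) ||
       (sat[2] && sat[3] && sat[4] && sat[5])) && prox
  }
  got <- pha_filter(poses, m)
  expect_equal(got$pass, vapply(poses, oracle_verdict, logical(1)))
  expect_gt(sum(got$pass), 0)
  expect_lt(sum(got$pass), length(poses))
})

test_that("enlarging radii never converts a pass into a fail", {
  fx <- fixture_pocket()
  m <- build_default_rorgt_model(fx$pocket$protein)
  big <- m
  big$points$radius <- big$points$radius + 2
  v1 <- pha_filter(fx$poses$poses, m)
  v2 <- pha_filter(fx$poses$poses, big)
  expect_true(all(v2$pass[v1$pass]))
})

test_that("verdicts are invariant under a joint rigid transform of pose and anchors", {
  fx <- fixture_pocket()
  m <- build_default_rorgt_model(fx$pocket$protein)
  R <- rotation_matrix(c(0.3, 1, 2), 1.1)
  shift <- c(5, -3, 2)
  poses <- fx$poses$poses[c(1, 2, 20, 21)]
  m_rot <- m
  m_rot$points <- rotate_df(m$points, R, shift)
  m_rot$proximity$anchors <- sweep(m$proximity$anchors %*% t(R), 2, shift, `+`)
  poses_rot <- lapply(poses, function(p) pose(p$compound_id, rotate_df(p$atoms, R, shift)))
  expect_equal(pha_filter(poses_rot, m_rot)$pass, pha_filter(poses, m)$pass)
})

test_that("compound verdicts OR over poses", {
  fx <- fixture_pocket()
  m <- build_default_rorgt_model(fx$pocket$protein)
  good <- fx$poses$poses[[1]]
  bad <- pose(good$compound_id, dplyr::mutate(good$atoms, x = x + 30), pose_id = 2L)
  v <- pha_filter(list(good, bad), m)
  cv <- pha_compound_verdicts(v)
  expect_equal(nrow(cv), 1)
  expect_true(cv$pass)
})
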