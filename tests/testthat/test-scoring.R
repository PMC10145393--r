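# Gaussian shape overlap, Hodgkin ESP similarity, and the blended
# rigid rescoring of docked poses.

test_that("shape_tanimoto is 1 for identical sets and ~0 for distant sets", {
  withr::with_seed(3, {
    a <- tibble::tibble(x = runif(5), y = runif(5), z = runif(5),
                        radius = runif(5, 1.2, 2))
  })
  expect_equal(shape_tanimoto(a, a), 1, tolerance = 1e-9)
  b <- dplyr::mutate(a, x = x + 100)
  expect_lt(shape_tanimoto(a, b), 1e-6)
  expect_error(shape_tanimoto(a[0, ], a), "non-empty")
})

test_that("analytic overlap matches 3-D grid quadrature on 2-atom bodies", {
  a <- tibble::tibble(x = c(0, 1.5), y = c(0, 0.3), z = 0, radius = c(1.7, 1.52))
  b <- tibble::tibble(x = c(0.8, 2.2), y = c(-0.4, 0.2), z = c(0.3, -0.1),
                      radius = c(1.55, 1.7))
  g <- oracle_grid_overlap(a, b, spacing = 0.12)
  t_grid <- g$oab / (g$oaa + g$obb - g$oab)
  t_analytic <- shape_tanimoto(a, b)
  expect_equal(t_analytic, t_grid, tolerance = 5e-3)  # 3 significant figures
})

test_that("shape_tanimoto is symmetric and rigid-motion invariant", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      a <- tibble::tibble(x = runif(4, -2, 2), y = runif(4, -2, 2),
                          z = runif(4, -2, 2), radius = runif(4, 1, 2))
      b <- tibble::tibble(x = runif(3, -2, 2), y = runif(3, -2, 2),
                          z = runif(3, -2, 2), radius = runif(3, 1, 2))
      expect_equal(shape_tanimoto(a, b), shape_tanimoto(b, a), tolerance = 1e-12)
      R <- rotation_matrix(runif(3), runif(1, 0, 2 * pi))
      shift <- runif(3, -5, 5)
      expect_equal(shape_tanimoto(rotate_df(a, R, shift), rotate_df(b, R, shift)),
                   shape_tanimoto(a, b), tolerance = 1e-9)
    }
  })
})

test_that("Hodgkin index hits +1/-1 at field identity/anti-identity and 0 when both vanish", {
  p <- pose("q", tibble::tibble(element = "N", x = 0, y = 0, z = 0, charge = 0.8))
  pts <- tibble::tibble(x = c(2, -3), y = 0, z = 0, kind = c("N", "O"))
  cfg <- score_config()
  # model charges set to the pose's own field at the points -> H = 1 exactly
  field <- c(0.8 / 2, 0.8 / 3)
  m_id <- nib_model(dplyr::mutate(pts, charge = field), filler_radius = 0.85)
  expect_equal(esp_hodgkin(p, m_id, cfg), 1)
  m_anti <- nib_model(dplyr::mutate(pts, charge = -field), filler_radius = 0.85)
  expect_equal(esp_hodgkin(p, m_anti, cfg), -1)
  # both fields zero -> defined as 0
  p0 <- pose("null", tibble::tibble(element = "C", x = 0, y = 0, z = 0, charge = 0))
  m0 <- nib_model(tibble::tibble(x = 2, y = 0, z = 0, kind = "C"), filler_radius = 0.85)
  expect_equal(esp_hodgkin(p0, m0, cfg), 0)
})

test_that("Hodgkin index equals the 4-term hand computation on the tabulated fixture", {
  # one +0.5 e atom; N point (+1) at 2.0 A, O point (-1) at 4.0 A
  p <- pose("q", tibble::tibble(element = "N", x = 0, y = 0, z = 0, charge = 0.5))
  m <- nib_model(tibble::tibble(x = c(2, 4), y = 0, z = 0, kind = c("N", "O")),
                 filler_radius = 0.85)
  e_pose <- c(0.5 / 2, 0.5 / 4)
  e_model <- c(1, -1)
  h_hand <- 2 * sum(e_pose * e_model) / (sum(e_pose^2) + sum(e_model^2))
  expect_equal(esp_hodgkin(p, m), h_hand, tolerance = 1e-12)
})

test_that("esp distance floor caps the Coulomb singularity", {
  p <- pose("q", tibble::tibble(element = "N", x = 0, y = 0, z = 0, charge = 1))
  m <- nib_model(tibble::tibble(x = 0.01, y = 0, z = 0, kind = "N"),
                 filler_radius = 0.85)
  # field evaluated at max(d, 1.0) = 1.0, not at 0.01
  expect_equal(esp_hodgkin(p, m), 2 * 1 / (1 + 1), tolerance = 1e-12)
})

test_that("nib_score degenerates to its components at the weight extremes", {
  fx <- fixture_pocket()
  model <- nib_create(fx$pocket$protein,
                      cavity_config(box_radius = 5, seed_point = fx$pocket$seed_point))
  p <- fx$poses$poses[[1]]
  heavy <- p$atoms[p$atoms$element != "H", ]
  t_only <- nib_score(p, model, score_config(w_shape = 1))
  expect_equal(t_only, shape_tanimoto(
    tibble::tibble(x = heavy$x, y = heavy$y, z = heavy$z,
                   radius = vdw_radius(heavy$element)),
    tibble::tibble(x = model$x, y = model$y, z = model$z,
                   radius = 2 * attr(model, "filler_radius"))), tolerance = 1e-12)
  # all charges zero -> blended score is w_shape * T
  p0 <- pose("nocharge", dplyr::mutate(p$atoms, charge = 0))
  expect_equal(nib_score(p0, model, score_config(w_shape = 0.5)),
               0.5 * t_only, tolerance = 1e-12)
})

test_that("the matched plug outscores the same pose displaced 3 A", {
  fx <- fixture_pocket()
  model <- nib_create(fx$pocket$protein,
                      cavity_config(box_radius = 5, seed_point = fx$pocket$seed_point))
  p <- fx$poses$poses[[1]]
  shifted <- pose(p$compound_id, dplyr::mutate(p$atoms, x = x + 3))
  expect_gt(nib_score(p, model), nib_score(shifted, model))
})

test_that("nib_score is monotone in w_shape in the direction of T - H", {
  fx <- fixture_pocket()
  model <- nib_create(fx$pocket$protein,
                      cavity_config(box_radius = 5, seed_point = fx$pocket$seed_point))
  p <- fx$poses$poses[[1]]
  s25 <- nib_score(p, model, score_config(w_shape = 0.25))
  s50 <- nib_score(p, model, score_config(w_shape = 0.5))
  s75 <- nib_score(p, model, score_config(w_shape = 0.75))
  t_ <- nib_score(p, model, score_config(w_shape = 1))
  h_ <- esp_hodgkin(p, model)
  if (t_ > h_) {
    expect_true(s25 < s50 && s50 < s75)
  } else {
    expect_true(s25 > s50 && s50 > s75)
  }
})

test_that("scoring mutates neither pose nor model", {
  fx <- fixture_pocket()
  model <- nib_create(fx$pocket$protein,
                      cavity_config(box_radius = 5, seed_point = fx$pocket$seed_point))
  p <- fx$poses$poses[[1]]
  atoms_before <- p$atoms
  model_before <- tibble::as_tibble(model)
  invisible(nib_score(p, model))
  expect_identical(p$atoms, atoms_before)
  expect_identical(tibble::as_tibble(model), model_before)
})

test_that("rescore_poses emits one record per pose and collapses to the best duplicate", {
  m <- nib_model(tibble::tibble(x = 0, y = 0, z = 0, kind = "C"), filler_radius = 0.85)
  poses <- lapply(1:10, function(k) {
    point_pose("cmpd", x = 0.2 * k, y = 0, z = 0, pose_id = k)
  })
  rec <- rescore_poses(poses, m)
  expect_equal(nrow(rec), 10)
  coll <- collapse_best_pose(rec)
  expect_equal(nrow(coll), 1)
  expect_equal(coll$score, max(rec$score))
  expect_equal(coll$pose_id, 1L)  # the least-displaced pose scores best

  # equal scores order by compound_id
  tie <- rescore_poses(list(point_pose("b", 1, 0, 0), point_pose("a", -1, 0, 0)), m)
  expect_equal(tie$compound_id, c("a", "b"))

  # 3-compound max oracle
  poses3 <- c(lapply(1:3, function(k) point_pose("x", 0.3 * k, 0, 0, pose_id = k)),
              lapply(1:2, function(k) point_pose("y", 0.5 * k, 0, 0, pose_id = k)),
              list(point_pose("z", 2, 0, 0)))
  rec3 <- rescore_poses(poses3, m)
  coll3 <- collapse_best_pose(rec3)
  brute <- tapply(rec3$score, rec3$compound_id, max)
  expect_equal(sort(coll3$score), sort(as.numeric(brute)))
})
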