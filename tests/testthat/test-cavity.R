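# FCC lattice generation, cavity carving, and mirror-image charge assignment.

test_that("FCC lattice has nearest-neighbour distance 2 * filler_radius", {
  lat <- generate_fcc_lattice(c(0, 0, 0), box_radius = 3, filler_radius = 0.85)
  d <- as.matrix(dist(lat[, c("x", "y", "z")]))
  diag(d) <- Inf
  expect_equal(min(d), 1.70, tolerance = 1e-12)
})

test_that("degenerate box collapses to the center point", {
  lat <- generate_fcc_lattice(c(1, 2, 3), box_radius = 0.5, filler_radius = 0.85)
  expect_equal(nrow(lat), 1)
  expect_equal(c(lat$x, lat$y, lat$z), c(1, 2, 3))
})

test_that("lattice point count matches exhaustive conventional-cell enumeration", {
  # oracle: enumerate conventional FCC cells (edge a = 2*sqrt(2)*r) with the
  # 4-point basis and count sites inside the cube
  r <- 0.85
  box <- 5
  a <- 2 * sqrt(2) * r
  basis <- rbind(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0))
  rng <- -ceiling(box / a):ceiling(box / a)
  pts <- NULL
  for (i in rng) for (j in rng) for (k in rng) {
    cand <- sweep(basis, 2, c(i, j, k), "+") * a
    keep <- abs(cand[, 1]) <= box + 1e-9 & abs(cand[, 2]) <= box + 1e-9 &
            abs(cand[, 3]) <= box + 1e-9
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- unique(round(pts, 9))
  lat <- generate_fcc_lattice(c(0, 0, 0), box_radius = box, filler_radius = r)
  expect_equal(nrow(lat), nrow(pts))
})

test_that("lattice ordering is deterministic and lexicographic in indices", {
  lat <- generate_fcc_lattice(c(0, 0, 0), 2, 0.85)
  expect_identical(lat, lat[order(lat$i, lat$j, lat$k), ])
})

# a tiny 8-atom "box pocket" protein used by the carving oracle tests
box8_protein <- function() {
  corners <- expand.grid(x = c(-3, 3), y = c(-3, 3), z = c(-3, 3))
  protein_structure(tibble::tibble(
    element = "C", x = corners$x, y = corners$y, z = corners$z,
    residue_name = "DUM", residue_number = 1L))
}

test_that("carving retains exactly the points passing the brute-force rule check", {
  prot <- box8_protein()
  cfg <- cavity_config(box_radius = 4, seed_point = c(0, 0, 0))
  lat <- generate_fcc_lattice(c(0, 0, 0), cfg$box_radius, cfg$filler_radius)
  model <- carve_cavity(lat, prot, cfg)

  # oracle: evaluate rules (a) no clash, (b) within range, per point; then
  # single connected component by full distance-matrix BFS
  pm <- as.matrix(lat[, c("x", "y", "z")])
  am <- as.matrix(prot[, c("x", "y", "z")])
  ok <- logical(nrow(pm))
  for (p in seq_len(nrow(pm))) {
    d <- sqrt(colSums((t(am) - pm[p, ])^2))
    ok[p] <- all(d >= 1.70 + 0.85) && any(d <= 4.5)
  }
  surv <- pm[ok, , drop = FALSE]
  dm <- as.matrix(dist(surv))
  adj <- dm <= 2 * 0.85 * (1 + 1e-6)
  comp <- rep(NA_integer_, nrow(surv))
  cur <- 0
  for (s in seq_len(nrow(surv))) {
    if (!is.na(comp[s])) next
    cur <- cur + 1
    frontier <- s
    comp[s] <- cur
    while (length(frontier) > 0) {
      nb <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nb] <- cur
      frontier <- nb
    }
  }
  seed_i <- which.min(rowSums(surv^2))
  expected <- surv[comp == comp[seed_i], , drop = FALSE]
  got <- as.matrix(model[, c("x", "y", "z")])
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
               expected[order(expected[, 1], expected[, 2], expected[, 3]), ],
               ignore_attr = TRUE)
  expect_true(all(model$kind == "C"))
})

test_that("points beyond max_protein_distance or inside the vdW envelope are removed", {
  prot <- protein_structure(tibble::tibble(
    element = "C", x = 0, y = 0, z = 0, residue_name = "DUM", residue_number = 1L))
  lat <- tibble::tibble(x = c(5.0, 0.5, 3.0), y = 0, z = 0)
  cfg <- cavity_config(seed_point = c(3, 0, 0))
  model <- carve_cavity(lat, prot, cfg)
  # 5.0 A away -> too far; 0.5 A -> clash (inside 1.70 + 0.85); 3.0 A survives
  expect_equal(nrow(model), 1)
  expect_equal(model$x, 3.0)
  expect_error(carve_cavity(tibble::tibble(x = 9, y = 0, z = 0), prot, cfg),
               "farther")
})

test_that("carving is idempotent and every point stays within range of the protein", {
  fx <- fixture_pocket()
  cfg <- cavity_config(box_radius = 6, seed_point = fx$pocket$seed_point)
  lat <- generate_fcc_lattice(fx$pocket$seed_point, cfg$box_radius, cfg$filler_radius)
  m1 <- carve_cavity(lat, fx$pocket$protein, cfg)
  m2 <- carve_cavity(m1, fx$pocket$protein, cfg)
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$x, m1$x)
  heavy <- heavy_atoms(fx$pocket$protein)
  hm <- as.matrix(heavy[, c("x", "y", "z")])
  for (p in seq_len(nrow(m1))) {
    expect_lte(min(sqrt(colSums((t(hm) - c(m1$x[p], m1$y[p], m1$z[p]))^2))), 4.5)
  }
})

test_that("jointly rotating protein, seed and lattice rotates the carved cavity", {
  fx <- fixture_pocket()
  cfg <- cavity_config(box_radius = 5, seed_point = fx$pocket$seed_point)
  lat <- generate_fcc_lattice(fx$pocket$seed_point, cfg$box_radius, cfg$filler_radius)
  base <- carve_cavity(lat, fx$pocket$protein, cfg)

  R <- rotation_matrix(c(1, 2, 0.5), 0.7)
  prot_r <- fx$pocket$protein
  prot_r[, c("x", "y", "z")] <- rotate_df(as.data.frame(prot_r), R)[, c("x", "y", "z")]
  lat_r <- rotate_df(lat, R)
  cfg_r <- cfg
  cfg_r$seed_point <- as.numeric(R %*% fx$pocket$seed_point)
  rot <- carve_cavity(lat_r, protein_structure(prot_r), cfg_r)
  base_rot <- as.matrix(base[, c("x", "y", "z")]) %*% t(R)
  got <- as.matrix(rot[, c("x", "y", "z")])
  expect_equal(nrow(rot), nrow(base))
  o1 <- order(round(base_rot[, 1], 6), round(base_rot[, 2], 6), round(base_rot[, 3], 6))
  o2 <- order(round(got[, 1], 6), round(got[, 2], 6), round(got[, 3], 6))
  expect_equal(got[o2, ], base_rot[o1, ], tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("charge assignment mirrors donors as O, acceptors as N, nearer partner wins", {
  mkprot <- function(atoms) protein_structure(atoms)
  m <- nib_model(tibble::tibble(x = 0, y = 0, z = 0, kind = "C"))
  cfg <- cavity_config()

  # backbone carbonyl O at 3.0 A, no donor -> positive N point
  acc <- mkprot(tibble::tibble(element = "O", x = 3, y = 0, z = 0,
                               residue_name = "GLY", residue_number = 1L,
                               atom_name = "O"))
  expect_equal(assign_point_charges(m, acc, cfg)$kind, "N")
  expect_equal(assign_point_charges(m, acc, cfg)$charge, 1)

  # nothing polar within 3.5 A -> stays neutral C
  far <- mkprot(tibble::tibble(element = "O", x = 4, y = 0, z = 0,
                               residue_name = "GLY", residue_number = 1L,
                               atom_name = "O"))
  expect_equal(assign_point_charges(m, far, cfg)$kind, "C")

  # water O (donor+acceptor) at 3.0 vs backbone amide N-H at 2.8 -> donor nearer -> O
  both <- mkprot(tibble::tibble(
    element = c("O", "N"), x = c(3, 2.8), y = 0, z = 0,
    residue_name = c("HOH", "ALA"), residue_number = c(770L, 1L),
    atom_name = c("O", "N")))
  expect_equal(assign_point_charges(m, both, cfg)$kind, "O")
  expect_equal(assign_point_charges(m, both, cfg)$charge, -1)

  # exact tie between donor and acceptor distances -> neutral C
  tie <- mkprot(tibble::tibble(
    element = c("O", "N"), x = c(3, -3), y = 0, z = 0,
    residue_name = c("GLY", "ALA"), residue_number = c(1L, 2L),
    atom_name = c("O", "N")))
  expect_equal(assign_point_charges(m, tie, cfg)$kind, "C")
})
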