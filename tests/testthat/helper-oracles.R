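# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation paths they test.

# BEDROC by direct summation of the defining formula on a plain score/label
# pair of vectors.
oracle_bedroc <- function(scores, labels, alpha = 20) {
  N <- length(scores)
  r <- rank(-scores, ties.method = "average")
  ri <- r[labels == "active"]
  n <- length(ri)
  if (n == N) return(1)
  ra <- n / N
  rie_num <- sum(exp(-alpha * ri / N)) / n
  rie_den <- (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- rie_num / rie_den
  rie * (ra * sinh(alpha / 2)) / (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

# AUC by explicit pairwise comparison counting (ties count one half).
oracle_auc <- function(scores, labels) {
  a <- scores[labels == "active"]
  d <- scores[labels == "decoy"]
  total <- 0
  for (x in a) total <- total + sum(x > d) + 0.5 * sum(x == d)
  total / (length(a) * length(d))
}

# Numerical 3-D grid quadrature of the Gaussian density overlap between two
# atom sets (sum of atom Gaussians each), on a regular grid.
oracle_grid_overlap <- function(a, b, p = 2.70, spacing = 0.15, pad = 4) {
  kappa <- pi * (3 * p / (4 * pi))^(2 / 3)
  all_pts <- rbind(as.matrix(a[, c("x", "y", "z")]), as.matrix(b[, c("x", "y", "z")]))
  lo <- apply(all_pts, 2, min) - pad
  hi <- apply(all_pts, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  density_of <- function(set) {
    rho <- numeric(nrow(grid))
    for (i in seq_len(nrow(set))) {
      alpha_i <- kappa / set$radius[i]^2
      d2 <- (grid[, 1] - set$x[i])^2 + (grid[, 2] - set$y[i])^2 + (grid[, 3] - set$z[i])^2
      rho <- rho + p * exp(-alpha_i * d2)
    }
    rho
  }
  ra <- density_of(a)
  rb <- density_of(b)
  cell <- spacing^3
  list(oab = sum(ra * rb) * cell, oaa = sum(ra * ra) * cell, obb = sum(rb * rb) * cell)
}

# Rotation matrix about an arbitrary axis (unit vector), angle in radians.
rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

rotate_df <- function(df, R, shift = c(0, 0, 0)) {
  m <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  df$x <- m[, 1] + shift[1]
  df$y <- m[, 2] + shift[2]
  df$z <- m[, 3] + shift[3]
  df
}

# Small labelled record table builder.
make_records <- function(scores_active, scores_decoy) {
  screen_records(tibble::tibble(
    compound_id = c(sprintf("A%03d", seq_along(scores_active)),
                    sprintf("D%03d", seq_along(scores_decoy))),
    score = c(scores_active, scores_decoy),
    label = rep(c("active", "decoy"), c(length(scores_active), length(scores_decoy)))
  ))
}

# One-atom pose at a location, optionally charged.
point_pose <- function(id, x, y, z, element = "C", charge = 0, pose_id = 1L) {
  pose(id, tibble::tibble(element = element, x = x, y = y, z = z,
                          charge = charge),
       pose_id = pose_id)
}

# Shared small fixture objects (built once per test run).
.fx <- new.env()
fixture_pocket <- function() {
  if (is.null(.fx$pocket)) {
    .fx$spec <- fixture_spec(seed = 11, n_actives = 12, n_decoys = 24)
    .fx$pocket <- make_box_pocket(.fx$spec)
    .fx$poses <- make_pose_set(.fx$spec, .fx$pocket)
  }
  list(spec = .fx$spec, pocket = .fx$pocket, poses = .fx$poses)
}

# Planted-noise setup: three model points near the origin fit the (slightly
# displaced) actives; a fourth "noise" point 6 A away coincides with the
# decoys, which outrank the actives until that point is deleted.
planted_fixture <- function() {
  model <- nib_model(tibble::tibble(
    x = c(0, 1.2, -1.2, 6),
    y = c(0, 0, 0, 0), z = 0,
    kind = "C"), filler_radius = 0.85)
  poses <- c(
    lapply(1:4, function(k) point_pose(sprintf("act%d", k), 0.05 * k, 1.8, 0)),
    lapply(1:8, function(k) point_pose(sprintf("dec%d", k), 6 + 0.05 * k, 0, 0))
  )
  list(model = model, poses = poses, actives = sprintf("act%d", 1:4))
}
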