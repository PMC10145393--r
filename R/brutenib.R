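# BR-NiB: greedy optimization of a NIB model by iterative single-point
# deletion, accepting at each generation the deletion that most improves the
# training-set BEDROC, until no deletion improves it.
#
# Per-variant scoring re-aggregates cached pose-vs-point contributions
# instead of rescoring, and is numerically identical to full rescoring
# (asserted in the test suite at 1e-12).

#' Evaluate a NIB model on a labelled training set
#'
#' Rescores every pose, collapses to the best pose per compound and returns
#' the BEDROC of the resulting ranking. A pure function: identical inputs
#' give the identical value.
#'
#' @param model A [nib_model()].
#' @param poses List of [pose()] objects (training poses).
#' @param actives Character vector of active compound IDs; the remaining
#'   compounds count as decoys.
#' @param alpha BEDROC sensitivity (default 20).
#' @param config A [score_config()].
#' @return The BEDROC value.
#' @export
evaluate_model <- function(model, poses, actives, alpha = 20,
                           config = score_config()) {
  records <- rescore_poses(poses, model, config, actives = actives)
  check_two_labels(records)
  bedroc(records, alpha = alpha)
}

check_two_labels <- function(records) {
  if (length(unique(records$label[records$label != "unknown"])) < 2) {
    abort("training set must contain both active and decoy compounds")
  }
  invisible(records)
}

# Pose-vs-point contribution cache. All quantities are indexed by the points
# of the *input* model so that any subset can be re-aggregated exactly.
build_score_cache <- function(model, poses, config) {
  pr <- config$point_radius %||% (2 * filler_radius(model))
  np <- nrow(model)
  pts <- coord_matrix(model)
  pose_tabs <- map(poses, pose_heavy_atoms)
  n_poses <- length(poses)
  P <- matrix(0, n_poses, np)    # pose-vs-point shape overlap
  E <- matrix(0, n_poses, np)    # pose Coulomb field at each point
  oaa <- numeric(n_poses)
  for (pidx in seq_len(n_poses)) {
    at <- pose_tabs[[pidx]]
    ca <- coord_matrix(at)
    ra <- vdw_radius(at$element)
    aa <- gaussian_alpha(ra, config$p)
    ab <- gaussian_alpha(pr, config$p)
    d2 <- outer(rowSums(ca^2), rowSums(pts^2), "+") - 2 * tcrossprod(ca, pts)
    d2[d2 < 0] <- 0
    s <- aa + ab
    P[pidx, ] <- colSums(config$p^2 * (pi / s)^1.5 * exp(-(aa * ab / s) * d2))
    oaa[pidx] <- gaussian_overlap(ca, ra, ca, ra, config$p)
    E[pidx, ] <- pose_field_at_points(at, pts, config)
  }
  M <- {
    ab <- gaussian_alpha(pr, config$p)
    d2 <- outer(rowSums(pts^2), rowSums(pts^2), "+") - 2 * tcrossprod(pts)
    d2[d2 < 0] <- 0
    config$p^2 * (pi / (2 * ab))^1.5 * exp(-(ab / 2) * d2)
  }
  list(P = P, E = E, E2 = E^2, EC = sweep(E, 2, model$charge, `*`),
       oaa = oaa, M = M, q = model$charge,
       compound = map_chr(poses, "compound_id"),
       config = config)
}

# Scores of all poses against the point subset `S` (logical), from the cache.
cache_scores <- function(cache, S) {
  oab <- rowSums(cache$P[, S, drop = FALSE])
  obb <- sum(cache$M[S, S])
  tt <- oab / (cache$oaa + obb - oab)
  cross <- rowSums(cache$EC[, S, drop = FALSE])
  sp <- rowSums(cache$E2[, S, drop = FALSE])
  sc <- sum(cache$q[S]^2)
  denom <- sp + sc
  h <- ifelse(denom == 0, 0, 2 * cross / denom)
  cache$config$w_shape * tt + cache$config$w_esp * h
}

cache_bedroc <- function(cache, scores, labels, alpha) {
  best <- tapply(scores, cache$compound, max)
  rec <- tibble(compound_id = names(best), entry_id = names(best),
                pose_id = 1L, score = as.numeric(best),
                label = labels[names(best)])
  bedroc(rec, alpha = alpha, collapse = FALSE)
}

#' Greedy BR-NiB optimization of a NIB model
#'
#' Per generation, every single-point-deletion variant of the incumbent
#' model is evaluated by training-set BEDROC; the best variant is accepted
#' if strictly better than the incumbent (ties among variants resolved to
#' the lowest point index of the input model), and the search stops when no
#' deletion improves the metric or one point remains. Deterministic given
#' its inputs.
#'
#' @inheritParams evaluate_model
#' @param max_generations Optional cap on accepted generations.
#' @return A `brutenib_run` with the input and final models, the accepted
#'   `history` (generation, removed point index in the input model, BEDROC)
#'   and the settings; has [tidy()], [glance()] and [autoplot()] methods.
#' @export
brutenib <- function(model, poses, actives, alpha = 20,
                     config = score_config(), max_generations = Inf) {
  if (nrow(model) < 2) abort("BR-NiB needs a model with at least 2 points")
  labels <- setNames(ifelse(unique(map_chr(poses, "compound_id")) %in% actives,
                            "active", "decoy"),
                     unique(map_chr(poses, "compound_id")))
  if (length(unique(labels)) < 2) {
    abort("training set must contain both active and decoy compounds")
  }
  cache <- build_score_cache(model, poses, config)
  S <- rep(TRUE, nrow(model))
  incumbent <- cache_bedroc(cache, cache_scores(cache, S), labels, alpha)
  history <- tibble(generation = 0L, removed_point_index = NA_integer_,
                    bedroc = incumbent)
  gen <- 0L
  while (sum(S) > 1 && gen < max_generations) {
    candidates <- which(S)
    metrics <- map_dbl(candidates, function(j) {
      S2 <- S
      S2[j] <- FALSE
      cache_bedroc(cache, cache_scores(cache, S2), labels, alpha)
    })
    best <- which.max(metrics)  # which.max takes the first (lowest index) tie
    if (metrics[best] <= incumbent) break
    S[candidates[best]] <- FALSE
    incumbent <- metrics[best]
    gen <- gen + 1L
    history <- bind_rows(history, tibble(
      generation = gen, removed_point_index = candidates[best],
      bedroc = incumbent))
  }
  structure(list(
    input_model = model,
    final_model = model[S, ],
    history = history,
    alpha = alpha, config = config,
    actives = actives
  ), class = "brutenib_run")
}

#' @export
print.brutenib_run <- function(x, ...) {
  cat(sprintf("<brutenib_run> %d -> %d points in %d generation(s); BEDROC%g %.4f -> %.4f\n",
              nrow(x$input_model), nrow(x$final_model),
              max(x$history$generation), x$alpha,
              x$history$bedroc[1], tail(x$history$bedroc, 1)))
  invisible(x)
}

#' @export
tidy.brutenib_run <- function(x, ...) x$history

#' @export
glance.brutenib_run <- function(x, ...) {
  tibble(points_in = nrow(x$input_model), points_out = nrow(x$final_model),
         generations = max(x$history$generation),
         bedroc_initial = x$history$bedroc[1],
         bedroc_final = tail(x$history$bedroc, 1), alpha = x$alpha)
}

#' Plot the BR-NiB optimization trajectory
#'
#' @param object A `brutenib_run`.
#' @param ... Ignored.
#' @return A ggplot of BEDROC against generation.
#' @export
autoplot.brutenib_run <- function(object, ...) {
  ggplot(object$history, aes(x = .data$generation, y = .data$bedroc)) +
    geom_line() + geom_point() +
    labs(x = "Generation (points removed)",
         y = sprintf("BEDROC%g", object$alpha)) +
    theme_minimal()
}

#' Reduce the active set by decoy-rank threshold
#'
#' For the second optimization round: actives scoring at or above the
#' score of the `ceiling(fraction * n_decoys)`-th best decoy are removed
#' (they are already well-ranked), and the remaining -- lowest-ranked --
#' active IDs are returned to retrain the model on the harder subset.
#'
#' @param records Labelled screen-record table scored under a given model.
#' @param fraction Decoy top fraction defining the threshold (default 0.01).
#' @return Character vector of retained active compound IDs (with a warning
#'   when empty).
#' @export
subset_actives_by_decoy_rank <- function(records, fraction = 0.01) {
  rec <- collapse_best_pose(records)
  dec <- sort(rec$score[rec$label == "decoy"], decreasing = TRUE)
  k <- ceiling(fraction * length(dec))
  if (length(dec) < 1 / fraction) {
    abort(sprintf("need at least %d decoys for a %.2g decoy-rank threshold",
                  ceiling(1 / fraction), fraction))
  }
  threshold <- dec[k]
  act <- rec[rec$label == "active", ]
  keep <- act$compound_id[act$score < threshold]
  if (length(keep) == 0) {
    warn("every active scores above the decoy threshold; the reduced active set is empty")
  }
  keep
}
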