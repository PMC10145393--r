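# Path-based (linear) molecular fingerprints with Daylight-style atom
# invariants, hashed into a fixed-width bit vector, plus Tanimoto
# similarity -- used for hit-novelty analysis against known ligands.

#' Daylight-style atom invariant
#'
#' Deterministic per-atom tuple used to label path atoms: element, heavy
#' degree, explicit attached-H count, formal-charge proxy (sign of the
#' partial charge when `|q| > 0.5`), in-ring flag and aromatic flag.
#'
#' @param pose A [pose()] with bonds.
#' @param index Atom index (may be a vector).
#' @return Character vector of invariant strings.
#' @export
atom_invariant <- function(pose, index = seq_len(nrow(pose$atoms))) {
  at <- pose$atoms
  b <- pose$bonds
  degree <- nh <- integer(nrow(at))
  if (nrow(b) > 0) {
    heavy <- is_heavy(at$element)
    for (r in seq_len(nrow(b))) {
      i <- b$i[r]; j <- b$j[r]
      if (heavy[j]) degree[i] <- degree[i] + 1L else nh[i] <- nh[i] + 1L
      if (heavy[i]) degree[j] <- degree[j] + 1L else nh[j] <- nh[j] + 1L
    }
  }
  chg <- ifelse(abs(at$charge) > 0.5, sign(at$charge), 0L)
  ring <- atom_in_ring(pose)
  sprintf("%s;d%d;h%d;c%+d;r%d;a%d",
          normalize_element(at$element), degree, nh, chg,
          as.integer(ring), as.integer(at$aromatic))[index]
}

# Ring membership: an atom is in a ring iff removing it leaves its bonded
# graph component intact -- computed via cycle detection on the heavy-atom
# graph (an edge is a ring edge iff its endpoints stay connected without it).
atom_in_ring <- function(pose) {
  n <- nrow(pose$atoms)
  b <- pose$bonds
  in_ring <- rep(FALSE, n)
  if (nrow(b) == 0) return(in_ring)
  adj <- map(seq_len(n), ~ integer(0))
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  connected_without <- function(from, to, skip_i, skip_j) {
    seen <- rep(FALSE, n)
    queue <- from
    seen[from] <- TRUE
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if ((v == skip_i && w == skip_j) || (v == skip_j && w == skip_i)) next
        if (!seen[w]) {
          if (w == to) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }
  for (r in seq_len(nrow(b))) {
    if (connected_without(b$i[r], b$j[r], b$i[r], b$j[r])) {
      in_ring[c(b$i[r], b$j[r])] <- TRUE
    }
  }
  in_ring
}

# Fixed, documented path hash: polynomial string hash with multiplier 31
# modulo 2^24 (exact in double arithmetic), reduced mod the bit width.
path_hash <- function(s, width) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (v in bytes) h <- (h * 31 + v) %% 16777216
  (h %% width) + 1L
}

#' 64-bit linear fingerprint of a molecule
#'
#' Enumerates all simple (non-atom-repeating) linear paths of 0 to
#' `max_path_bonds` bonds over the heavy-atom graph, canonicalizes each
#' path string (atom invariants joined by bond orders, lexicographically
#' smaller direction), hashes it to a bit position and ORs it in.
#'
#' @param pose A [pose()].
#' @param max_path_bonds Maximum path length in bonds (default 7).
#' @param width Bit-vector width (default 64; collision-prone by design at
#'   that width, configurable).
#' @return A `fingerprint`: logical vector of `width` bits with attribute
#'   `n_set`.
#' @export
linear_fingerprint <- function(pose, max_path_bonds = 7, width = 64) {
  paths <- linear_paths(pose, max_path_bonds)
  bits <- rep(FALSE, width)
  for (s in unique(paths)) bits[path_hash(s, width)] <- TRUE
  structure(bits, n_set = sum(bits), class = "fingerprint")
}

# Canonical path strings (lexicographically smaller direction) of all simple
# linear paths over the heavy-atom graph, one entry per traversal start, so
# each undirected path appears twice before deduplication.
linear_paths <- function(pose, max_path_bonds = 7) {
  at <- pose$atoms
  heavy_idx <- which(is_heavy(at$element))
  inv <- atom_invariant(pose)
  b <- pose$bonds
  bonds <- b[is_heavy(at$element[b$i]) & is_heavy(at$element[b$j]), , drop = FALSE]
  adj <- map(seq_len(nrow(at)), ~ integer(0))
  bord <- new.env(parent = emptyenv())
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
      assign(paste(i, j), bonds$order[r], envir = bord)
      assign(paste(j, i), bonds$order[r], envir = bord)
    }
  }
  paths <- character(0)
  emit <- function(atom_path) {
    parts <- character(2 * length(atom_path) - 1)
    parts[seq_along(atom_path) * 2 - 1] <- inv[atom_path]
    if (length(atom_path) > 1) {
      for (s in seq_len(length(atom_path) - 1)) {
        parts[2 * s] <- get(paste(atom_path[s], atom_path[s + 1]), envir = bord)
      }
    }
    fwd <- paste(parts, collapse = "|")
    rev_ <- paste(rev(parts), collapse = "|")
    paths[[length(paths) + 1]] <<- if (fwd <= rev_) fwd else rev_
  }
  walk_from <- function(path) {
    emit(path)
    if (length(path) > max_path_bonds) return(invisible())
    tip <- path[length(path)]
    for (w in adj[[tip]]) {
      if (!w %in% path) walk_from(c(path, w))
    }
  }
  for (a in heavy_idx) walk_from(a)
  paths
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d/%d bits set\n", attr(x, "n_set"), length(x)))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; two empty fingerprints are defined as 0, so
#' completely different and identical molecules score 0 and 1 respectively.
#'
#' @param a,b Fingerprints of equal width.
#' @return Similarity in `[0, 1]`.
#' @export
fp_tanimoto <- function(a, b) {
  if (length(a) != length(b)) abort("fingerprint widths differ")
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Maximum Tanimoto similarity against a reference set
#'
#' The novelty statistic: for each query molecule, the largest Tanimoto
#' coefficient against any reference molecule (values below ~0.2 indicate
#' structural novelty).
#'
#' @param poses List of query [pose()] objects.
#' @param ref_poses List of reference poses (e.g. known ligands).
#' @param max_path_bonds,width Passed to [linear_fingerprint()].
#' @return Tibble with `compound_id`, `max_tanimoto` and the closest
#'   reference's `nearest_ref`.
#' @export
fp_max_similarity <- function(poses, ref_poses, max_path_bonds = 7, width = 64) {
  fps <- map(poses, linear_fingerprint, max_path_bonds = max_path_bonds, width = width)
  ref_fps <- map(ref_poses, linear_fingerprint, max_path_bonds = max_path_bonds, width = width)
  list_rbind(imap(fps, function(fp, k) {
    sims <- map_dbl(ref_fps, fp_tanimoto, a = fp)
    best <- which.max(sims)
    tibble(compound_id = poses[[as.integer(k)]]$compound_id,
           max_tanimoto = sims[best],
           nearest_ref = ref_poses[[best]]$compound_id)
  }))
}
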