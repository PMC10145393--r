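# Pose: one docked 3D conformation of a compound entry. Atoms and bonds are
# tibbles; properties is a named character map carrying things like logP or
# binding-energy annotations. Bond order 4 encodes an aromatic bond.

#' Construct a docked pose
#'
#' @param compound_id Parent compound identifier (vendor/database ID).
#' @param atoms Tibble with `element`, `x`, `y`, `z` and optionally `charge`
#'   (partial charge, e; default 0) and `aromatic` (logical; default FALSE).
#' @param bonds Tibble with `i`, `j` (1-based atom indices) and `order`
#'   (1, 2, 3, or 4 = aromatic). May be `NULL` for a bond-less point set.
#' @param entry_id Identifier distinguishing tautomer/enantiomer variants of
#'   the compound; defaults to `compound_id`.
#' @param pose_id Integer pose index within the entry.
#' @param properties Named character vector of free-form annotations.
#' @return A `pose` object.
#' @examples
#' pose("cmpd-1", tibble::tibble(element = "C", x = 0, y = 0, z = 0))
#' @export
pose <- function(compound_id, atoms, bonds = NULL, entry_id = compound_id,
                 pose_id = 1L, properties = character()) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) < 1) abort("a pose needs at least one atom")
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"aromatic" %in% names(atoms)) atoms$aromatic <- FALSE
  atoms$charge[is.na(atoms$charge)] <- 0
  atoms$element <- normalize_element(atoms$element)
  if (is.null(bonds)) bonds <- tibble(i = integer(), j = integer(), order = integer())
  bonds <- as_tibble(bonds)
  if (nrow(bonds) > 0 &&
      (any(bonds$i < 1 | bonds$i > nrow(atoms)) ||
       any(bonds$j < 1 | bonds$j > nrow(atoms)))) {
    abort("bond endpoints must index valid atoms")
  }
  structure(
    list(compound_id = as.character(compound_id),
         entry_id = as.character(entry_id),
         pose_id = as.integer(pose_id),
         atoms = atoms, bonds = bonds,
         properties = properties),
    class = "pose"
  )
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %s (entry %s, pose %d): %d atoms, %d bonds, %d properties\n",
              x$compound_id, x$entry_id, x$pose_id,
              nrow(x$atoms), nrow(x$bonds), length(x$properties)))
  invisible(x)
}

pose_heavy_atoms <- function(p) p$atoms[is_heavy(p$atoms$element), ]

#' Read a multi-record SDF file into a list of poses
#'
#' Parses V2000 records via ChemmineR. Data fields become the pose's
#' `properties` map. Aromatic atom flags are taken from bond type 4 where
#' present; records without any aromatic bond fall back to ring perception
#' (atoms of rings that ChemmineR classifies aromatic are flagged).
#' Per-atom partial charges are read from an `ATOM_CHARGES` data field
#' (whitespace-separated, one value per atom) when present; otherwise all
#' charges are zero and a warning is emitted once per file, in which case the
#' electrostatic term of any downstream score contributes nothing.
#'
#' Identity: `compound_id` is the record title; `entry_id` comes from an
#' `ENTRY_ID` field (default: the title) and `pose_id` from a `POSE_ID`
#' field (default: running count within the entry). Malformed records are
#' skipped with a warning naming how many were dropped.
#'
#' @param path Path to an SDF file.
#' @return A list of [pose()] objects.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) abort(paste0("SDF file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  ends <- which(str_trim(lines) == "$$$$")
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  records <- map2(starts, ends, ~ lines[.x:.y])
  records <- keep(records, ~ any(nzchar(str_trim(.x))))

  parsed <- map(records, parse_sdf_record)
  n_bad <- sum(map_lgl(parsed, is.null))
  parsed <- compact(parsed)
  if (length(parsed) == 0) abort(paste0("no parsable V2000 records in ", path))
  if (n_bad > 0) {
    warn(sprintf("skipped %d malformed SDF record(s) in %s", n_bad, basename(path)))
  }
  no_charge_seen <- FALSE
  poses <- vector("list", length(parsed))
  counters <- new.env(parent = emptyenv())
  for (k in seq_along(parsed)) {
    rec <- parsed[[k]]
    atoms <- rec$atoms
    bonds <- rec$bonds
    props <- rec$props
    if ("ATOM_CHARGES" %in% names(props)) {
      q <- suppressWarnings(as.numeric(strsplit(str_trim(props[["ATOM_CHARGES"]]), "\\s+")[[1]]))
      if (length(q) == nrow(atoms) && !anyNA(q)) atoms$charge <- q
    } else {
      no_charge_seen <- TRUE
    }
    atoms$aromatic <- perceive_aromatic(rec$raw, atoms, bonds)
    if ("AROMATIC_ATOMS" %in% names(props)) {
      idx <- suppressWarnings(as.integer(strsplit(str_trim(props[["AROMATIC_ATOMS"]]), "\\s+")[[1]]))
      atoms$aromatic[idx[!is.na(idx) & idx <= nrow(atoms)]] <- TRUE
    }
    title <- rec$title
    if (!nzchar(title)) title <- paste0("mol", k)
    compound_id <- title
    entry_id <- if ("ENTRY_ID" %in% names(props)) props[["ENTRY_ID"]] else compound_id
    key <- paste(compound_id, entry_id, sep = "\r")
    if ("POSE_ID" %in% names(props)) {
      pose_id <- as.integer(props[["POSE_ID"]])
    } else {
      pose_id <- (get0(key, envir = counters, ifnotfound = 0L)) + 1L
      assign(key, pose_id, envir = counters)
    }
    poses[[k]] <- pose(compound_id, atoms, bonds, entry_id = entry_id,
                       pose_id = pose_id, properties = props)
  }
  if (no_charge_seen) {
    warn(sprintf("%s: no ATOM_CHARGES field on some records; their partial charges are all zero",
                 basename(path)))
  }
  poses
}

# One V2000 record -> atoms/bonds/properties, or NULL when malformed.
# Fixed-column parsing per the V2000 layout; data fields run to the next
# blank line.
parse_sdf_record <- function(rec) {
  rec <- rec[str_trim(rec) != "$$$$"]
  if (length(rec) < 5) return(NULL)
  na <- suppressWarnings(as.integer(substr(rec[4], 1, 3)))
  nb <- suppressWarnings(as.integer(substr(rec[4], 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1 || length(rec) < 4 + na + nb) return(NULL)
  al <- rec[5:(4 + na)]
  x <- suppressWarnings(as.numeric(substr(al, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(al, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(al, 21, 30)))
  element <- str_trim(substr(al, 31, 34))
  if (anyNA(x) || anyNA(y) || anyNA(z) || any(!nzchar(element))) return(NULL)
  bonds <- tibble(i = integer(), j = integer(), order = integer())
  if (nb > 0) {
    bl <- rec[(5 + na):(4 + na + nb)]
    i <- suppressWarnings(as.integer(substr(bl, 1, 3)))
    j <- suppressWarnings(as.integer(substr(bl, 4, 6)))
    o <- suppressWarnings(as.integer(substr(bl, 7, 9)))
    if (anyNA(i) || anyNA(j) || anyNA(o)) return(NULL)
    bonds <- tibble(i = i, j = j, order = o)
  }
  props <- character()
  for (s in grep("^>", rec)) {
    key <- sub("^>\\s*<([^>]*)>.*$", "\\1", rec[s])
    vals <- character()
    t <- s + 1
    while (t <= length(rec) && nzchar(str_trim(rec[t]))) {
      vals <- c(vals, rec[t])
      t <- t + 1
    }
    props[[key]] <- paste(vals, collapse = "\n")
  }
  list(title = str_trim(rec[1]),
       atoms = tibble(element = element, x = x, y = y, z = z,
                      charge = 0, aromatic = FALSE),
       bonds = bonds, props = props, raw = rec)
}

# Aromatic flags: explicit bond type 4 wins; else atoms of rings ChemmineR
# classifies aromatic (alternating single/double perception) are flagged.
perceive_aromatic <- function(raw, atoms, bonds) {
  arom <- rep(FALSE, nrow(atoms))
  if (!is.null(bonds) && nrow(bonds) > 0 && any(bonds$order == 4L)) {
    idx <- unique(c(bonds$i[bonds$order == 4L], bonds$j[bonds$order == 4L]))
    arom[idx] <- TRUE
    return(arom)
  }
  if (is.null(bonds) || nrow(bonds) == 0) return(arom)
  rr <- tryCatch({
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    writeLines(c(raw, "$$$$"), tmp)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
    suppressWarnings(ChemmineR::rings(sdfset[[1]], type = "all", arom = TRUE))
  }, error = function(e) NULL)
  if (is.null(rr) || length(rr$RINGS) == 0) return(arom)
  for (nm in names(rr$RINGS)) {
    if (isTRUE(rr$AROMATIC[[nm]])) {
      idx <- as.integer(sub("^.*_", "", rr$RINGS[[nm]]))
      arom[idx] <- TRUE
    }
  }
  arom
}

#' Write poses to a multi-record V2000 SDF file
#'
#' Inverse of [read_sdf()]: aromatic bonds are written as bond type 4,
#' partial charges as an `ATOM_CHARGES` data field, and the pose identity as
#' `ENTRY_ID`/`POSE_ID` fields, so a write/read cycle reproduces the pose.
#'
#' @param poses A [pose()] or list of poses.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(poses, path) {
  if (inherits(poses, "pose")) poses <- list(poses)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    a <- p$atoms
    b <- p$bonds
    lines <- c(
      p$compound_id, "  nibscreen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              a$x, a$y, a$z, a$element)
    )
    if (nrow(b) > 0) {
      lines <- c(lines, sprintf("%3d%3d%3d  0", b$i, b$j, b$order))
    }
    lines <- c(lines, "M  END")
    props <- p$properties
    props[["ENTRY_ID"]] <- p$entry_id
    props[["POSE_ID"]] <- as.character(p$pose_id)
    if (any(p$atoms$charge != 0)) {
      props[["ATOM_CHARGES"]] <- paste(format(a$charge, trim = TRUE), collapse = " ")
    }
    # atom aromaticity is not representable in V2000 without aromatic bonds
    if (any(a$aromatic) && !any(b$order == 4L)) {
      props[["AROMATIC_ATOMS"]] <- paste(which(a$aromatic), collapse = " ")
    }
    for (nm in names(props)) {
      lines <- c(lines, sprintf("> <%s>", nm), props[[nm]], "")
    }
    writeLines(c(lines, "$$$$"), con)
  }
  invisible(path)
}
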