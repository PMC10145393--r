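# NIBModel: the negative image of a binding cavity -- a cloud of pseudo-atom
# points, each neutral (C), positively charged (N) or negatively charged (O),
# with a uniform filler radius. This is the unit that greedy optimization
# edits and that poses are scored against.

#' Construct a NIB model
#'
#' @param points Tibble with `x`, `y`, `z` (Angstrom) and `kind`
#'   (`"C"`, `"N"`, or `"O"`). A `charge` column may be supplied; if absent
#'   charges follow the kind: C = 0, N = `+q`, O = `-q`.
#' @param filler_radius Radius (Angstrom) of the packing spheres the points
#'   were placed with; must be positive.
#' @param provenance Free-text metadata (kept through read/write).
#' @param q Magnitude of the point charge assigned to N/O kinds.
#' @return A `nib_model` tibble with attributes `filler_radius` and
#'   `provenance`.
#' @examples
#' nib_model(tibble::tibble(x = 0, y = 0, z = 0, kind = "N"), filler_radius = 0.85)
#' @export
nib_model <- function(points, filler_radius = 0.85, provenance = "", q = 1) {
  points <- as_tibble(points)
  if (nrow(points) > 0 && !all(points$kind %in% c("C", "N", "O"))) {
    bad <- unique(points$kind[!points$kind %in% c("C", "N", "O")])
    abort(paste0("NIB point kinds must be C, N or O; found: ", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(filler_radius) || filler_radius <= 0) {
    abort("filler_radius must be positive")
  }
  if (!"charge" %in% names(points)) {
    points$charge <- c(C = 0, N = q, O = -q)[points$kind]
    points$charge <- unname(points$charge)
  }
  points <- points[, c("x", "y", "z", "kind", "charge")]
  attr(points, "filler_radius") <- filler_radius
  attr(points, "provenance") <- provenance
  class(points) <- c("nib_model", class(tibble()))
  points
}

#' @export
print.nib_model <- function(x, ...) {
  cat(sprintf("<nib_model> %d points (%d C / %d N / %d O), filler radius %.2f A\n",
              nrow(x), sum(x$kind == "C"), sum(x$kind == "N"), sum(x$kind == "O"),
              attr(x, "filler_radius")))
  invisible(x)
}

filler_radius <- function(model) attr(model, "filler_radius")

# Subsetting a nib_model keeps its attributes.
#' @export
`[.nib_model` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("x", "y", "z", "kind", "charge") %in% names(out))) {
    attr(out, "filler_radius") <- attr(x, "filler_radius")
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- class(x)
  }
  out
}

#' Read / write a NIB model as a MOL2 point file
#'
#' NIB models travel as MOL2 files whose `@<TRIPOS>ATOM` records are the
#' cavity points, atom-typed `C`/`N`/`O` with their charges in the charge
#' column. The round trip is lossless to 0.0001 Angstrom in coordinates and
#' bit-identical in kinds and charges (at the written 4-decimal precision).
#'
#' @param path File path.
#' @param model A [nib_model()].
#' @param q Charge magnitude used when a file row carries no charge column.
#' @return `read_nib_model`: a `nib_model`; `write_nib_model`: `path`,
#'   invisibly.
#' @export
read_nib_model <- function(path, q = 1) {
  if (!file.exists(path)) abort(paste0("NIB model file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  iat <- which(str_trim(lines) == "@<TRIPOS>ATOM")
  if (length(iat) == 0) abort(paste0("no @<TRIPOS>ATOM section in ", path))
  imol <- which(str_trim(lines) == "@<TRIPOS>MOLECULE")
  provenance <- if (length(imol) > 0 && length(lines) > imol[1]) str_trim(lines[imol[1] + 1]) else ""
  body <- lines[(iat[1] + 1):length(lines)]
  stop_at <- which(str_detect(str_trim(body), "^@<TRIPOS>"))
  if (length(stop_at) > 0) body <- body[seq_len(stop_at[1] - 1)]
  body <- body[nzchar(str_trim(body))]
  if (length(body) == 0) abort(paste0("empty @<TRIPOS>ATOM section in ", path))
  fields <- str_split(str_trim(body), "\\s+")
  parse_row <- function(f, row) {
    if (length(f) < 6) abort(sprintf("malformed MOL2 atom record %d in %s", row, path))
    kind <- sub("\\..*$", "", f[6])
    if (!kind %in% c("C", "N", "O")) {
      abort(sprintf("unknown NIB point kind '%s' in record %d of %s", f[6], row, path))
    }
    tibble(x = as.numeric(f[3]), y = as.numeric(f[4]), z = as.numeric(f[5]),
           kind = kind,
           charge = if (length(f) >= 9) as.numeric(f[9]) else NA_real_)
  }
  pts <- list_rbind(imap(fields, parse_row))
  if (anyNA(pts$charge)) {
    pts$charge <- NULL  # let the constructor assign kind-derived charges
  }
  fr <- 0.85
  rad_line <- grep("^# filler_radius", lines, value = TRUE)
  if (length(rad_line) > 0) fr <- as.numeric(sub("^# filler_radius\\s*", "", rad_line[1]))
  nib_model(pts, filler_radius = fr, provenance = provenance, q = q)
}

#' @rdname read_nib_model
#' @export
write_nib_model <- function(model, path) {
  stopifnot(inherits(model, "nib_model"))
  n <- nrow(model)
  lines <- c(
    sprintf("# filler_radius %.4f", filler_radius(model)),
    "@<TRIPOS>MOLECULE",
    if (nzchar(attr(model, "provenance"))) attr(model, "provenance") else "NIB_model",
    sprintf("%5d %5d     0     0     0", n, 0),
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("%7d %-4s %10.4f %10.4f %10.4f %-5s %5d %-8s %10.4f",
            seq_len(n), paste0(model$kind, seq_len(n)),
            model$x, model$y, model$z, model$kind, 1L, "NIB", model$charge)
  )
  writeLines(lines, path)
  invisible(path)
}
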