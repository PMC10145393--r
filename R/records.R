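# ScreenRecord tables: one row per scored pose with an activity label.
# Every ranking and enrichment computation in the package runs on this shape.

#' Construct a screen-record table
#'
#' @param records Data frame with `compound_id`, `entry_id`, `pose_id`,
#'   `score` (finite) and `label` (`"active"`, `"decoy"` or `"unknown"`).
#'   Missing `entry_id`/`pose_id`/`label` columns are filled with defaults.
#' @return A tibble with the five canonical columns.
#' @export
screen_records <- function(records) {
  records <- as_tibble(records)
  if (!"entry_id" %in% names(records)) records$entry_id <- records$compound_id
  if (!"pose_id" %in% names(records)) records$pose_id <- 1L
  if (!"label" %in% names(records)) records$label <- "unknown"
  required <- c("compound_id", "entry_id", "pose_id", "score", "label")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("screen records lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(records$score))) abort("all scores must be finite")
  if (!all(records$label %in% c("active", "decoy", "unknown"))) {
    abort("labels must be 'active', 'decoy' or 'unknown'")
  }
  key <- paste(records$compound_id, records$entry_id, records$pose_id)
  if (anyDuplicated(key)) abort("(compound_id, entry_id, pose_id) must be unique")
  records[, union(required, names(records))]
}

#' Collapse records to one row per compound (best pose)
#'
#' Duplicates of a compound -- alternative tautomers, enantiomers and docking
#' poses -- are collapsed to the best-scoring representative, the convention
#' used for every compound-level decision in the screening funnel.
#' Output is ordered by score (descending), ties broken by `compound_id`.
#'
#' @param records A screen-record table.
#' @return A tibble with one row per `compound_id`.
#' @export
collapse_best_pose <- function(records) {
  records %>%
    group_by(.data$compound_id) %>%
    arrange(desc(.data$score), .data$entry_id, .data$pose_id, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(desc(.data$score), .data$compound_id)
}

#' Read / write screen-record TSV files
#'
#' Plain TSV with columns `compound_id`, `entry_id`, `pose_id`, `score`,
#' `label`.
#'
#' @param path File path.
#' @param records A screen-record table.
#' @return `read_records`: a validated tibble; `write_records`: `path`,
#'   invisibly.
#' @export
read_records <- function(path) {
  screen_records(readr::read_tsv(path, show_col_types = FALSE,
                                 col_types = readr::cols(
                                   compound_id = "c", entry_id = "c",
                                   pose_id = "i", score = "d", label = "c")))
}

#' @rdname read_records
#' @export
write_records <- function(records, path) {
  readr::write_tsv(screen_records(records), path)
  invisible(path)
}

#' Apply activity labels from ID lists
#'
#' @param records A screen-record table.
#' @param actives Character vector of active compound IDs.
#' @param decoys Optional character vector of decoy IDs; every compound not
#'   in `actives` is labelled `"decoy"` when `decoys` is `NULL`.
#' @return The relabelled table.
#' @export
label_records <- function(records, actives, decoys = NULL) {
  records$label <- ifelse(records$compound_id %in% actives, "active",
                          if (is.null(decoys)) "decoy"
                          else ifelse(records$compound_id %in% decoys, "decoy", "unknown"))
  records
}
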