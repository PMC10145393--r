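# Compound-selection funnel: per-model top-fraction cut, pooling across
# models, then property threshold filters (logP, pattern exclusions,
# binding-energy) with a per-rule exclusion log.

#' Funnel settings
#'
#' @param top_fraction Top fraction of each per-model ranking to carry
#'   forward (default 0.01).
#' @param logp_max Compounds with logP strictly above this are excluded
#'   (default 5.5; the boundary value itself is retained).
#' @param energy_max Compounds with predicted binding energy (kcal/mol)
#'   strictly above this are excluded (default -95; more negative = better).
#' @param logp_key,energy_key Property-map keys carrying the values.
#' @param pattern_ids Character vector of compound IDs matched by an
#'   external pattern screen (e.g. PAINS); matched compounds are excluded.
#' @param missing_policy What to do when a property is absent:
#'   `"exclude"` (default, logged) or `"keep"` (with a warning).
#' @return A `funnel_config` list.
#' @export
funnel_config <- function(top_fraction = 0.01, logp_max = 5.5,
                          energy_max = -95, logp_key = "ALOGP",
                          energy_key = "MMGBSA", pattern_ids = character(),
                          missing_policy = c("exclude", "keep")) {
  if (top_fraction <= 0 || top_fraction > 1) abort("top_fraction must lie in (0, 1]")
  structure(list(top_fraction = top_fraction, logp_max = logp_max,
                 energy_max = energy_max, logp_key = logp_key,
                 energy_key = energy_key, pattern_ids = pattern_ids,
                 missing_policy = match.arg(missing_policy)),
            class = "funnel_config")
}

#' Select the top fraction of a per-compound ranking
#'
#' Takes the best `floor(fraction * N)` compounds (at least one) by
#' descending score, ties broken by `compound_id`.
#'
#' @param records Screen-record table collapsed to one row per compound.
#' @param fraction Fraction in `(0, 1]`.
#' @return The selected rows, in rank order.
#' @examples
#' # a 169,100-compound ranking yields 1,691 selected compounds at 1%
#' @export
select_top_fraction <- function(records, fraction = 0.01) {
  if (nrow(records) == 0) abort("no records to select from")
  if (anyDuplicated(records$compound_id)) {
    abort("records must be collapsed to one row per compound (see collapse_best_pose)")
  }
  k <- max(1L, floor(fraction * nrow(records)))
  records %>%
    arrange(desc(.data$score), .data$compound_id) %>%
    head(k)
}

#' Pool per-model selections
#'
#' Concatenates the per-model selections as "entries" (cross-model
#' duplicates retained and flagged) and derives the deduplicated compound
#' set keeping each compound's best score.
#'
#' @param selections List of per-model selected record tables (optionally
#'   named by model).
#' @return List with `entries` (all rows, with a `model` column and a
#'   `duplicate` flag on repeated compounds) and `compounds` (unique
#'   compounds, best score each).
#' @export
pool_models <- function(selections) {
  if (length(selections) == 0) abort("pool_models needs at least one selection")
  nms <- names(selections) %||% as.character(seq_along(selections))
  if (is.null(names(selections))) names(selections) <- nms
  entries <- list_rbind(imap(selections, ~ mutate(.x, model = .y))) %>%
    group_by(.data$compound_id) %>%
    mutate(duplicate = n() > 1) %>%
    ungroup()
  compounds <- entries %>%
    group_by(.data$compound_id) %>%
    arrange(desc(.data$score), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(desc(.data$score), .data$compound_id)
  list(entries = entries, compounds = compounds)
}

#' Apply the funnel's property threshold filters
#'
#' Three rules, each strict (`>` excludes, the boundary value survives):
#' logP above `logp_max`; binding energy above `energy_max`; compound ID on
#' the pattern-exclusion list. Exclusions are attributed to the first rule
#' that fires (pattern, then logP, then energy) and logged per record;
#' unparsable numeric properties are logged and excluded.
#'
#' @param records Record table with a `properties` list-column (named
#'   character vectors, as carried by poses) or plain `logp`/`energy`
#'   columns.
#' @param config A [funnel_config()].
#' @return List with `survivors` (record tibble) and `log` (tibble of
#'   `compound_id`, `rule`, `value`).
#' @export
threshold_filters <- function(records, config = funnel_config()) {
  get_prop <- function(row_props, key, col) {
    if (!is.null(col)) return(col)
    map_chr(row_props, ~ .x[key] %||% NA_character_)
  }
  props <- if ("properties" %in% names(records)) records$properties else NULL
  logp_raw <- if ("logp" %in% names(records)) as.character(records$logp)
              else get_prop(props, config$logp_key, NULL)
  energy_raw <- if ("energy" %in% names(records)) as.character(records$energy)
                else get_prop(props, config$energy_key, NULL)
  logp <- suppressWarnings(as.numeric(logp_raw))
  energy <- suppressWarnings(as.numeric(energy_raw))

  n <- nrow(records)
  rule <- rep(NA_character_, n)
  value <- rep(NA_character_, n)
  flag <- function(idx, rule_name, val) {
    fresh <- idx & is.na(rule)
    rule[fresh] <<- rule_name
    value[fresh] <<- as.character(val)[fresh]
  }
  flag(records$compound_id %in% config$pattern_ids, "pattern", records$compound_id)
  bad_logp <- !is.na(logp_raw) & is.na(logp)
  flag(bad_logp, "logp_unparsable", logp_raw)
  missing_logp <- is.na(logp_raw)
  if (config$missing_policy == "exclude") {
    flag(missing_logp, "logp_missing", logp_raw)
  } else if (any(missing_logp)) {
    warn(sprintf("%d record(s) lack a %s property; kept", sum(missing_logp), config$logp_key))
  }
  flag(!is.na(logp) & logp > config$logp_max, "logp", logp)
  bad_energy <- !is.na(energy_raw) & is.na(energy)
  flag(bad_energy, "energy_unparsable", energy_raw)
  missing_energy <- is.na(energy_raw)
  if (config$missing_policy == "exclude") {
    flag(missing_energy, "energy_missing", energy_raw)
  } else if (any(missing_energy)) {
    warn(sprintf("%d record(s) lack a %s property; kept", sum(missing_energy), config$energy_key))
  }
  flag(!is.na(energy) & energy > config$energy_max, "energy", energy)

  excluded <- !is.na(rule)
  list(
    survivors = records[!excluded, , drop = FALSE],
    log = tibble(compound_id = records$compound_id[excluded],
                 rule = rule[excluded], value = value[excluded])
  )
}

#' Summarise a hit table from an experimental screen
#'
#' Counts, over the tested (non-control) compounds of a screening results
#' table: how many showed any measurable inhibition, how many have
#' well-defined IC50 values (measurable and not flagged as rough
#' estimates), the IC50 range bounds, and the effective hit rate
#' (well-defined hits over compounds tested).
#'
#' @param hits Tibble with columns `compound` (`"control"` rows are
#'   ignored), `ic50_um` (numeric, `NA` = no detectable binding or
#'   non-soluble) and `ic50_estimate` (logical: minimum signal not reached,
#'   value is a rough estimate).
#' @return One-row tibble: `n_tested`, `n_inhibitors`, `n_hits`,
#'   `ic50_min`, `ic50_max`, `hit_rate_pct` (rounded to the nearest
#'   percent) and `hit_rate_raw_pct`.
#' @export
summarize_hits <- function(hits) {
  tested <- hits[tolower(hits$compound) != "control", , drop = FALSE]
  measured <- tested[!is.na(tested$ic50_um), , drop = FALSE]
  well <- measured[!measured$ic50_estimate, , drop = FALSE]
  rate <- 100 * nrow(well) / nrow(tested)
  tibble(
    n_tested = nrow(tested),
    n_inhibitors = nrow(measured),
    n_hits = nrow(well),
    ic50_min = min(measured$ic50_um),
    ic50_max = max(measured$ic50_um),
    hit_rate_pct = round(rate),
    hit_rate_raw_pct = rate
  )
}

#' Path to the packaged RORgamma-t screening results table
#'
#' A machine-readable copy of the experimental outcome of the 28-compound
#' RORgamma-t screen: reporter-assay IC50 values (with no-binding /
#' non-soluble / rough-estimate annotations), predicted MM/GBSA binding
#' energies and maximum fingerprint similarity to known ligands.
#'
#' @return File path of the TSV inside the installed package.
#' @export
rorgt_screen_results_path <- function() {
  system.file("extdata", "rorgt_screen_results.tsv", package = "nibscreen",
              mustWork = TRUE)
}

#' Read the packaged screening results table
#'
#' @return Tibble with `compound`, `specs_id`, `ic50_um`, `ic50_estimate`,
#'   `status`, `mmgbsa_kcal`, `max_tanimoto`.
#' @export
read_rorgt_screen_results <- function() {
  readr::read_tsv(rorgt_screen_results_path(), show_col_types = FALSE,
                  col_types = readr::cols(
                    compound = "c", specs_id = "c", ic50_um = "d",
                    ic50_estimate = "l", status = "c",
                    mmgbsa_kcal = "d", max_tanimoto = "d"))
}
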