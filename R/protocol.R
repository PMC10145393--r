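# End-to-end screening protocol: cavity model -> rescoring -> greedy
# optimization -> top-fraction cut -> pharmacophore filter -> property
# funnel, with a manifest recording per-stage counts.

#' Run the full screening protocol
#'
#' Executes, in order: (1) cavity NIB-model generation, (2) in-place
#' rescoring of the poses, (3) greedy BR-NiB optimization on the labelled
#' training poses, (4) top-fraction compound selection under the optimized
#' model, (5) pharmacophore filtering of the selected compounds' poses,
#' (6) property threshold filters. Stage 1 may be skipped by supplying a
#' ready-made model. Stage counts are reported in a manifest: stage 1 in
#' cavity-point units, stages 2-6 in compound units, chaining consistently
#' from one stage to the next.
#'
#' @param config Named list (or path to a YAML file holding one) with
#'   entries: `protein` (a [protein_structure()] or PDB path), `poses`
#'   (list of poses or SDF path), `actives` (IDs or path to a one-per-line
#'   list), optional `nib_model` (model or MOL2 path; skips stage 1),
#'   `seed_point`/`seed_ligand`, `cavity` ([cavity_config()] arguments),
#'   `score` ([score_config()] arguments), `alpha` (default 20),
#'   `top_fraction` (default 0.01), `funnel` ([funnel_config()] arguments),
#'   `water_residue` (default 770), `out_dir` (optional artifact
#'   directory).
#' @return A `protocol_result`: list with `manifest` (stage tibble),
#'   `model`, `optimized` (a `brutenib_run`), `records`, `selected`,
#'   `verdicts`, `survivors`, `funnel_log` and `bedroc`.
#' @export
run_protocol <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  protein <- cfg$protein
  if (is.character(protein)) protein <- read_pdb(protein)
  poses <- cfg$poses
  if (is.character(poses)) {
    if (!file.exists(poses)) abort("protocol stage 2 (rescore): poses file not found")
    poses <- read_sdf(poses)
  }
  if (is.null(poses) || length(poses) == 0) {
    abort("protocol stage 2 (rescore): no poses supplied")
  }
  actives <- cfg$actives
  if (is.character(actives) && length(actives) == 1 && file.exists(actives)) {
    actives <- readLines(actives)
  }
  if (!is.null(cfg$seed_point)) cfg$seed_point <- as.numeric(unlist(cfg$seed_point))
  sc <- do.call(score_config, cfg$score %||% list())
  alpha <- cfg$alpha %||% 20
  top_fraction <- cfg$top_fraction %||% 0.01
  fc <- do.call(funnel_config, c(list(top_fraction = top_fraction),
                                 cfg$funnel %||% list()))

  manifest <- tibble(stage = character(), status = character(),
                     n_in = integer(), n_out = integer(),
                     wall_time_s = numeric(), detail = character())
  note <- function(stage, status, n_in, n_out, t0, detail = "") {
    manifest <<- bind_rows(manifest, tibble(
      stage = stage, status = status, n_in = as.integer(n_in),
      n_out = as.integer(n_out),
      wall_time_s = round(as.numeric(Sys.time()) - t0, 3), detail = detail))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("protocol stage failed: ", stage, " -- ", conditionMessage(e)))
    })
  }

  # stage 1: cavity model (point units)
  t0 <- as.numeric(Sys.time())
  if (!is.null(cfg$nib_model)) {
    model <- cfg$nib_model
    if (is.character(model)) model <- read_nib_model(model)
    note("nib-create", "skipped (provided)", nrow(model), nrow(model), t0)
  } else {
    cav <- do.call(cavity_config, c(cfg$cavity %||% list(),
                                    list(seed_point = cfg$seed_point)))
    model <- run_stage("nib-create", {
      if (is.null(protein)) abort("no protein supplied")
      nib_create(protein, cav, seed_ligand = cfg$seed_ligand)
    })
    lat_n <- nrow(generate_fcc_lattice(cfg$seed_point %||% c(0, 0, 0),
                                       cav$box_radius, cav$filler_radius))
    note("nib-create", "ok", lat_n, nrow(model), t0,
         sprintf("%d cavity points", nrow(model)))
  }

  n_compounds <- length(unique(map_chr(poses, "compound_id")))

  # stage 2: rescore (compound units)
  t0 <- as.numeric(Sys.time())
  records <- run_stage("rescore", rescore_poses(poses, model, sc, actives = actives))
  note("rescore", "ok", n_compounds, n_compounds, t0,
       sprintf("%d poses scored", length(poses)))

  # stage 3: BR-NiB optimization
  t0 <- as.numeric(Sys.time())
  opt <- run_stage("brutenib", brutenib(model, poses, actives, alpha = alpha, config = sc))
  records <- run_stage("brutenib", rescore_poses(poses, opt$final_model, sc, actives = actives))
  note("brutenib", "ok", n_compounds, n_compounds, t0,
       sprintf("%d -> %d points, BEDROC%g %.3f", nrow(model),
               nrow(opt$final_model), alpha, tail(opt$history$bedroc, 1)))

  # stage 4: top-fraction selection
  t0 <- as.numeric(Sys.time())
  compounds <- collapse_best_pose(records)
  selected <- run_stage("top-fraction", select_top_fraction(compounds, top_fraction))
  note("top-fraction", "ok", nrow(compounds), nrow(selected), t0,
       sprintf("top %g%%", 100 * top_fraction))

  # stage 5: pharmacophore filter on the selected compounds' poses
  t0 <- as.numeric(Sys.time())
  pha <- run_stage("pha-filter", {
    m <- cfg$pha_model %||% build_default_rorgt_model(protein, cfg$water_residue %||% 770)
    sel_poses <- keep(poses, ~ .x$compound_id %in% selected$compound_id)
    pha_filter(sel_poses, m)
  })
  passed <- pha_compound_verdicts(pha)
  passed_ids <- passed$compound_id[passed$pass]
  note("pha-filter", "ok", nrow(selected), length(passed_ids), t0)

  # stage 6: property funnel
  t0 <- as.numeric(Sys.time())
  funnel_in <- selected[selected$compound_id %in% passed_ids, , drop = FALSE]
  prop_of <- setNames(map(poses, "properties"), map_chr(poses, "compound_id"))
  funnel_in$properties <- prop_of[funnel_in$compound_id]
  filtered <- run_stage("funnel", threshold_filters(funnel_in, fc))
  note("funnel", "ok", nrow(funnel_in), nrow(filtered$survivors), t0,
       paste0(nrow(filtered$log), " excluded"))

  result <- structure(list(
    manifest = manifest, model = model, optimized = opt,
    records = records, selected = selected, verdicts = pha,
    survivors = filtered$survivors, funnel_log = filtered$log,
    bedroc = tail(opt$history$bedroc, 1)
  ), class = "protocol_result")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nib_model(opt$final_model, file.path(cfg$out_dir, "optimized_model.mol2"))
    write_records(records, file.path(cfg$out_dir, "records.tsv"))
    readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
    readr::write_tsv(pha, file.path(cfg$out_dir, "pha_verdicts.tsv"))
    readr::write_tsv(filtered$survivors[, setdiff(names(filtered$survivors), "properties")],
                     file.path(cfg$out_dir, "survivors.tsv"))
  }
  result
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>\n")
  print(x$manifest[, c("stage", "status", "n_in", "n_out", "detail")])
  invisible(x)
}
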