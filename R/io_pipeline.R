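#' Read a cohort CSV
#'
#' Reads and validates a patient-level cohort file with columns
#' `patient_id`, `histology`, `t`, `n`, `m`, `time_months`, `event`.
#' Malformed rows are rejected with their (1-based data) row numbers;
#' missing columns are named.
#'
#' @param path Path to a CSV file with a header row.
#' @return Validated cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "histology", "t", "n", "m", "time_months",
            "event")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tm <- suppressWarnings(as.numeric(d$time_months))
  bad <- which(!is.finite(tm) | tm < 0)
  if (length(bad))
    stop("invalid time_months at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  d$time_months <- tm
  ev <- suppressWarnings(as.integer(d$event))
  bad <- which(is.na(ev) | !(ev %in% 0:1))
  if (length(bad))
    stop("invalid event at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  d$event <- ev
  for (col in c("histology", "t", "n", "m")) {
    lev <- switch(col, histology = .histologies,
                  t = c(.t_fine, .t_coarse), n = .n_levels,
                  m = c(.m_fine, .m_coarse))
    bad <- which(!(d[[col]] %in% lev))
    if (length(bad))
      stop("invalid ", col, " value at data row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  d[need]
}

#' Write a cohort CSV
#'
#' @param records Cohort data.frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(records, path) {
  .check_full_cohort(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input A cohort data.frame or a `sim_config` to simulate from.
#' @param outdir Output directory (created if needed).
#' @param grid_step Monthly grid spacing for KM curves.
#' @param min_group_size Minimum patients per clustered subgroup.
#' @param linkage Agglomeration linkage.
#' @param k_substage Number of modified sub-stages.
#' @param stage_pattern Sub-stages per stage; must sum to `k_substage`.
#' @param bootstrap_B Bootstrap replicates for evaluation CIs.
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input, outdir, grid_step = 1,
                            min_group_size = 30, linkage = "average",
                            k_substage = 8, stage_pattern = c(2, 2, 3, 1),
                            bootstrap_B = 1000, seed = 1L) {
  stopifnot(grid_step > 0, min_group_size > 0, k_substage > 0,
            bootstrap_B >= 0, sum(stage_pattern) == k_substage)
  structure(list(input = input, outdir = outdir, grid_step = grid_step,
                 min_group_size = min_group_size, linkage = linkage,
                 k_substage = k_substage, stage_pattern = stage_pattern,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Named substream seeds derived from the master seed, so each stochastic
# stage is independently reproducible.
.substream <- function(seed, k) as.integer((seed + 1000003 * k) %% 2147483647)

#' Run the full staging-modification pipeline
#'
#' End-to-end run: obtain the cohort (simulating it if `input` is a
#' `sim_config`), stage every patient under the 8th-edition and published
#' modified maps, build per-subgroup KM curves, the curve-distance matrix
#' and the dendrogram, cut it into modified sub-stages, derive the
#' data-driven stage map, and evaluate the 8th-edition and derived systems.
#' Artifacts are written to `outdir`:
#'
#' * `staged_cohort.csv` — per-patient 8th, published-modified and derived
#'   sub-stage/stage labels
#' * `subgroup_curves.tsv` — long-format KM curves per subgroup
#' * `distance_matrix.tsv` — labelled curve-distance matrix
#' * `dendrogram.nwk` — Newick cluster tree
#' * `stage_map_derived.json` — derived map with entry provenance
#' * `evaluation_ajcc8.json`, `evaluation_derived.json` — reports
#' * `manifest.json` — config, seeds and artifact list
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the in-memory results and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$outdir, f)

  cohort <- if (inherits(config$input, "sim_config")) {
    simulate_cohort(config$input)
  } else {
    .check_full_cohort(config$input)
    config$input
  }

  map8 <- stage_map_8th()
  mapp <- stage_map_paper_modified()
  lk8 <- stage_lookup(map8, cohort$histology, cohort$t, cohort$n, cohort$m)
  lkp <- stage_lookup(mapp, cohort$histology, cohort$t, cohort$n, cohort$m)
  staged <- cohort
  staged$substage_8th <- lk8$substage
  staged$stage_8th <- lk8$stage
  staged$substage_paper <- lkp$substage
  staged$stage_paper <- lkp$stage

  set <- build_curve_set(cohort, config$min_group_size, config$grid_step)
  dm <- build_distance_matrix(set)
  tree <- agglomerate(dm, config$linkage)
  rg <- cut_and_label(tree, set, config$k_substage, config$stage_pattern)
  mapd <- derive_stage_map(rg, complete = TRUE)
  lkd <- stage_lookup(mapd, cohort$histology, cohort$t, cohort$n, cohort$m)
  staged$substage_derived <- lkd$substage
  staged$stage_derived <- lkd$stage

  utils::write.csv(staged, path("staged_cohort.csv"), row.names = FALSE,
                   quote = FALSE)
  curves_long <- do.call(rbind, lapply(names(set$curves), function(lb) {
    cv <- set$curves[[lb]]
    data.frame(subgroup = lb, time_months = cv$time, survival = cv$surv,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(curves_long, path("subgroup_curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(subgroup = rownames(dm), dm,
                                check.names = FALSE),
                     path("distance_matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(export_newick(tree), path("dendrogram.nwk"))
  write_stage_map(mapd, path("stage_map_derived.json"))

  rep8 <- evaluation_report(cohort, map8, B = config$bootstrap_B,
                            seed = .substream(config$seed, 1))
  repd <- evaluation_report(cohort, mapd, B = config$bootstrap_B,
                            seed = .substream(config$seed, 2))
  jsonlite::write_json(rep8, path("evaluation_ajcc8.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(repd, path("evaluation_derived.json"),
                       auto_unbox = TRUE, digits = NA)

  artifacts <- c("staged_cohort.csv", "subgroup_curves.tsv",
                 "distance_matrix.tsv", "dendrogram.nwk",
                 "stage_map_derived.json", "evaluation_ajcc8.json",
                 "evaluation_derived.json", "manifest.json")
  manifest <- list(
    package = "survregroup",
    version = as.character(utils::packageVersion("survregroup")),
    seed = config$seed,
    substreams = list(evaluation_8th = .substream(config$seed, 1),
                      evaluation_derived = .substream(config$seed, 2)),
    config = list(grid_step = config$grid_step,
                  min_group_size = config$min_group_size,
                  linkage = config$linkage,
                  k_substage = config$k_substage,
                  stage_pattern = config$stage_pattern,
                  bootstrap_B = config$bootstrap_B,
                  simulated = inherits(config$input, "sim_config")),
    n_patients = nrow(cohort),
    excluded_subgroups = set$excluded,
    artifacts = artifacts)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(cohort = staged, curve_set = set, distance = dm,
                 tree = tree, regrouping = rg, derived_map = mapd,
                 reports = list(ajcc8 = rep8, derived = repd),
                 paths = stats::setNames(as.list(file.path(config$outdir,
                                                           artifacts)),
                                         artifacts)))
}
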