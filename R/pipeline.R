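# End-to-end orchestration: simulate -> enrich -> compare-nutrients ->
# coverage -> describe -> evaluate, with plain files between stages and a
# JSON manifest recording outputs, parameters and file checksums.

#' Run the full pipeline from a single configuration
#'
#' Stages run in dependency order; every stage writes plain CSV/JSON files
#' under `out_dir` so any stage can be re-run or inspected from its
#' persisted inputs alone. A manifest (`manifest.json`) records the
#' configuration hash, per-stage row counters and the MD5 checksum of
#' every file produced; re-running with the same configuration reproduces
#' identical outputs.
#'
#' @param config Either a `cohort_config`, a path to a YAML file with
#'   blocks `cohort`, `enrichment` (optional weight/threshold overrides)
#'   and `coverage` (optional `k`, `subset_sizes`), or a list of those
#'   blocks.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- normalize_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), files = character())
  stamp <- function(stage, info, files) {
    manifest$stages[[stage]] <<- info
    manifest$files <<- union(manifest$files, files)
  }

  # stage 1: simulate
  sim_dir <- file.path(out_dir, "simulated")
  cohort <- generate_cohort(cfg$cohort, out_dir = sim_dir)
  stamp("simulate",
        list(n_lines = nrow(cohort$purchases),
             n_receipts = count_receipts(cohort$purchases),
             n_products = nrow(cohort$products)),
        list.files(sim_dir, full.names = TRUE))

  # stage 2: enrich
  enr <- enrich(cohort$purchases, cohort$generic_db, cohort$specific_dbs,
                cfg$enrichment)
  match_path <- file.path(out_dir, "matches.csv")
  lines_path <- file.path(out_dir, "enriched_lines.csv")
  queue_path <- file.path(out_dir, "review_queue.csv")
  summ_path <- file.path(out_dir, "enrichment_summary.json")
  write_table(enr$matches, match_path)
  write_table(enr$lines, lines_path)
  write_table(export_review_queue(enr), queue_path)
  jsonlite::write_json(as.list(enr$summary), summ_path, auto_unbox = TRUE,
                       digits = NA)
  stamp("enrich", as.list(enr$summary),
        c(match_path, lines_path, queue_path, summ_path))

  # stage 3: compare nutrients
  comp <- compare_nutrients(enr, cohort$generic_db, cohort$specific_dbs)
  comp_path <- file.path(out_dir, "nutrient_comparisons.csv")
  med_path <- file.path(out_dir, "nutrient_group_medians.csv")
  write_table(comp, comp_path)
  write_table(group_medians(comp, cohort$generic_db), med_path)
  cdf_paths <- purrr::map_chr(
    unique(comp$nutrient), function(nut) {
      p <- file.path(out_dir, paste0("cdf_", nut, ".csv"))
      write_table(rel_diff_cdf(comp, nut), p)
      p
    })
  stamp("compare_nutrients",
        list(n_comparisons = nrow(comp),
             n_excluded = attr(comp, "n_excluded")),
        c(comp_path, med_path, cdf_paths))

  # stage 4: retailer coverage
  groups <- top_food_groups(enr$lines, k = cfg$coverage$k)
  cov <- coverage_differences(enr$lines, groups)
  cov_path <- file.path(out_dir, "coverage_differences.csv")
  disp_path <- file.path(out_dir, "coverage_dispersion.csv")
  pct_path <- file.path(out_dir, "coverage_percentiles.csv")
  write_table(cov, cov_path)
  write_table(dispersion_summary(cov), disp_path)
  write_table(percentile_summary(cov), pct_path)
  stamp("coverage",
        list(n_groups = length(groups), n_rows = nrow(cov)),
        c(cov_path, disp_path, pct_path))

  # stage 5: descriptives
  desc <- summarize_cohort(cohort$purchases)
  desc_path <- file.path(out_dir, "cohort_summary.csv")
  write_table(desc$summary, desc_path)
  stamp("describe", list(n_participants = nrow(desc$per_participant)),
        desc_path)

  # stage 6: evaluation against truth
  ev <- evaluate_matching(enr, cohort$truth$observed_products,
                          cohort$generic_db)
  ev_path <- file.path(out_dir, "matching_evaluation.json")
  conf_path <- file.path(out_dir, "matching_confusion.csv")
  jsonlite::write_json(as.list(ev$rates), ev_path, auto_unbox = TRUE,
                       digits = NA)
  write_table(ev$confusion, conf_path)
  stamp("evaluate", as.list(ev$rates), c(ev_path, conf_path))

  manifest$config_hash <- unname(tools::md5sum(
    write_manifest_config(cfg, out_dir)))
  manifest$file_md5 <- as.list(tools::md5sum(sort(manifest$files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

normalize_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "cohort_config")) {
    config <- list(cohort = config)
  }
  cohort <- config$cohort %||% cohort_config()
  if (!inherits(cohort, "cohort_config")) {
    cohort <- do.call(cohort_config, cohort)
  }
  enr <- config$enrichment %||% enrich_config()
  if (!inherits(enr, "enrich_config")) {
    enr <- do.call(enrich_config, enr)
  }
  cov <- config$coverage %||% list()
  cov$k <- cov$k %||% 20
  list(cohort = cohort, enrichment = enr, coverage = cov)
}

write_manifest_config <- function(cfg, out_dir) {
  path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(list(
    cohort = unclass(cfg$cohort),
    enrichment = lapply(unclass(cfg$enrichment), function(x) {
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
    }),
    coverage = cfg$coverage
  ), path)
  path
}
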