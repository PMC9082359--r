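# End-to-end pipeline: geometry -> compartments -> metrics -> molecular
# classification -> group statistics, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with the published
#' defaults: 10/50 um band thresholds, 15 um merge radius with 5-cell
#' minimum cluster support, cluster-area density denominators, CPS cap 100
#' with positivity at >= 1, HRDetect thresholds 0.9 (germline, inclusive),
#' 0.9 (somatic, exclusive) and 0.7 (low-cellularity, exclusive), MSIsensor
#' cutoff 20, and two-sided tests with the exact Wilcoxon branch up to a
#' combined n of 20.
#'
#' @param intra_max,peri_max Compartment band limits (um).
#' @param merge_radius,min_cells Cluster reconstruction, see
#'   [build_tumor_clusters()].
#' @param cps_cap,cps_threshold CPS upper cap and positivity cutoff.
#' @param hrdetect_germline,hrdetect_somatic,hrdetect_low_cellularity,msisensor_cutoff
#'   Classifier thresholds, see [classify_case()].
#' @param exact_max_n Largest combined sample size for the exact Wilcoxon
#'   branch.
#' @param p_adjust `"none"` or `"BH"`.
#' @param groups The two subgroups compared.
#' @param survival_exclude Case ids excluded from survival analysis only.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(intra_max = 10, peri_max = 50,
                            merge_radius = 15, min_cells = 5,
                            cps_cap = 100, cps_threshold = 1,
                            hrdetect_germline = 0.9, hrdetect_somatic = 0.9,
                            hrdetect_low_cellularity = 0.7,
                            msisensor_cutoff = 20,
                            exact_max_n = 20, p_adjust = "none",
                            groups = c("HR_d", "HR_MMR_intact"),
                            survival_exclude = character(), seed = 1L) {
  thresholds <- zone_thresholds(intra_max, peri_max)  # validates the band
  if (merge_radius <= 0 || min_cells < 1) {
    abort("merge_radius must be positive and min_cells >= 1.",
          class = "immunozone_error_config")
  }
  if (cps_cap <= 0 || cps_threshold < 0) {
    abort("cps_cap must be positive and cps_threshold >= 0.",
          class = "immunozone_error_config")
  }
  for (th in c(hrdetect_germline, hrdetect_somatic, hrdetect_low_cellularity)) {
    if (th < 0 || th > 1) {
      abort("HRDetect thresholds must lie in [0, 1].",
            class = "immunozone_error_config")
    }
  }
  structure(list(thresholds = thresholds, merge_radius = merge_radius,
                 min_cells = min_cells, cps_cap = cps_cap,
                 cps_threshold = cps_threshold,
                 hrdetect_germline = hrdetect_germline,
                 hrdetect_somatic = hrdetect_somatic,
                 hrdetect_low_cellularity = hrdetect_low_cellularity,
                 msisensor_cutoff = msisensor_cutoff,
                 exact_max_n = exact_max_n, p_adjust = p_adjust,
                 groups = groups, survival_exclude = survival_exclude,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: tumor-cluster geometry, compartment assignment, immune
#' metrics, molecular classification, group statistics.  Intermediates are
#' written when `output_dir` is given (zoned metrics and labels as TSV, the
#' report as JSON) together with a manifest recording the configuration
#' hash, seed, and per-stage row counts; re-running on identical inputs
#' reproduces identical outputs.
#'
#' @param cells Cohort cell table (see [read_cell_table()]).
#' @param annotations Molecular annotation table (see [classify_table()]).
#' @param clinical Optional tibble with `case_id`, `time_months`, `event`
#'   for survival analysis.
#' @param exclusions Optional named list `core_id` -> exclusion rings.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for intermediate artifacts.
#' @return List with `profiles` (`immune_profiles`), `labels`, `report`
#'   (`cohort_comparison`) and `manifest`.
#' @export
run_pipeline <- function(cells, annotations, clinical = NULL,
                         exclusions = NULL, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cells <- validate_cell_table(cells)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "immunozone_error_pipeline", parent = e)
    })
  }

  profiles <- stage("spatial_metrics", profile_cases(
    cells, exclusions = exclusions, thresholds = config$thresholds,
    merge_radius = config$merge_radius, min_cells = config$min_cells,
    cps_threshold = config$cps_threshold
  ))
  labels <- stage("molecular_classify", classify_table(
    annotations,
    hrdetect_germline = config$hrdetect_germline,
    hrdetect_somatic = config$hrdetect_somatic,
    hrdetect_low_cellularity = config$hrdetect_low_cellularity,
    msisensor_cutoff = config$msisensor_cutoff
  ))
  report <- stage("cohort_stats", compare_cohort(
    profiles, labels, survival = clinical, groups = config$groups,
    survival_exclude = config$survival_exclude, p_adjust = config$p_adjust
  ))

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    n_cells = nrow(cells),
    n_cores = dplyr::n_distinct(cells$core_id),
    n_cases = dplyr::n_distinct(cells$case_id),
    n_evaluable_cores = dplyr::n_distinct(profiles$cores$core_id),
    dropped_cores = profiles$dropped_cores,
    n_annotated = nrow(labels),
    subgroup_counts = as.list(table(labels$subgroup))
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(profiles$densities,
                     file.path(output_dir, "case_densities.tsv"))
    readr::write_tsv(profiles$scores, file.path(output_dir, "case_scores.tsv"))
    readr::write_tsv(labels, file.path(output_dir, "subgroup_labels.tsv"))
    jsonlite::write_json(report_as_list(report),
                         file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(profiles = profiles, labels = labels, report = report,
       manifest = manifest)
}

# Stable hash of the configuration (order-independent content digest).
config_hash <- function(config) {
  rlang::hash(config[order(names(config))])
}

report_as_list <- function(report) {
  list(
    groups = report$groups,
    densities = report$densities,
    scores = report$scores,
    pdl1_positivity = report$pdl1_positivity,
    survival = if (!is.null(report$survival)) {
      list(medians = report$survival$medians,
           logrank_p = report$survival$p_value)
    }
  )
}
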