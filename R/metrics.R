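# Per-case immune metrics: compartment densities normalized to tumor-cluster
# area, replicate-core averaging, the log10 floor transform for zero counts,
# the CD8+:FOXP3+ ratio, and the PD-L1 Combined Positive Score.

#' Immune-cell density
#'
#' @param count Cell count(s).
#' @param area_mm2 Tumor-cluster area (mm^2); must be positive (cores with
#'   zero tumor area are excluded upstream).
#' @return Density in cells/mm^2.
#' @export
cell_density <- function(count, area_mm2) {
  if (any(!is.finite(area_mm2)) || any(area_mm2 <= 0)) {
    abort("`area_mm2` must be positive; cores without tumor area are excluded.",
          class = "immunozone_error_area")
  }
  count / area_mm2
}

#' Average a metric across replicate tumor cores
#'
#' @param x Per-core values; `NA` marks unevaluable cores.
#' @return Arithmetic mean of the evaluable cores, or `NA` if none.
#' @export
aggregate_replicates <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

#' Log10 transform with a floor for zero counts
#'
#' Cases with a value of zero are assigned 90% of the lowest non-zero value
#' across the cases evaluated, then everything is log10-transformed.  The
#' floor guarantees zeros plot strictly below every observed value.
#'
#' @param x Non-negative values (one per case); must include a non-zero.
#' @return `log10` of the floored values.
#' @examples
#' log_floor_transform(c(A = 0, B = 10, C = 100))
#' @export
log_floor_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    abort("Values must be non-negative.", class = "immunozone_error_input")
  }
  nz <- x[!is.na(x) & x > 0]
  if (length(nz) == 0L) {
    abort("All values are zero: the log floor is undefined.",
          class = "immunozone_error_input")
  }
  floor_val <- 0.9 * min(nz)
  log10(ifelse(!is.na(x) & x == 0, floor_val, x))
}

#' Case-level CD8+:FOXP3+ ratio
#'
#' The per-core ratio divides the total CD8+ count by the total FOXP3+ count
#' (all compartments combined).  Cores without any FOXP3+ cell have an
#' undefined ratio and are excluded from the case mean rather than given an
#' infinite value or a pseudocount.
#'
#' @param cd8,foxp3 Whole-core CD8+ and FOXP3+ totals, one element per
#'   replicate core.
#' @return Mean per-core ratio across evaluable cores, or `NA` if no core
#'   has a positive FOXP3+ count.
#' @examples
#' cd8_foxp3_ratio(c(10, 8), c(0, 2))  # first core excluded -> 4
#' @export
cd8_foxp3_ratio <- function(cd8, foxp3) {
  stopifnot(length(cd8) == length(foxp3))
  ok <- !is.na(cd8) & !is.na(foxp3) & foxp3 > 0
  if (!any(ok)) return(NA_real_)
  mean(cd8[ok] / foxp3[ok])
}

#' PD-L1 Combined Positive Score for one core
#'
#' CPS = 100 x (PD-L1-positive tumor cells + lymphocytes + macrophages) /
#' (viable tumor cells), capped at 100.  Cores without viable tumor cells
#' are unevaluable (`NA`).
#'
#' @param cells Cell records for one core, with `cps_class`,
#'   `pdl1_positive` and `viable` columns.
#' @param cap Upper cap (default 100, the conventional clinical maximum).
#' @return CPS for the core, or `NA` if unevaluable.
#' @export
cps <- function(cells, cap = 100) {
  stopifnot(is.data.frame(cells))
  viable <- cells[cells$viable, , drop = FALSE]
  denom <- sum(viable$cps_class == "tumor_cell")
  if (denom == 0L) return(NA_real_)
  num <- sum(viable$pdl1_positive &
               viable$cps_class %in% c("tumor_cell", "lymphocyte", "macrophage"))
  min(100 * num / denom, cap)
}

#' Compartment areas within a core boundary
#'
#' Areas (mm^2) of the intra-tumoral, peri-tumoral and stromal regions:
#' morphological dilations of the tumor clusters by the band thresholds,
#' clipped to the core boundary.  Used as denominators when per-compartment
#' intensities (rather than cluster-area-normalized densities) are wanted,
#' e.g. for parameter-recovery checks against the simulator.
#'
#' @param clusters A non-empty `tumor_clusters` object.
#' @param thresholds [zone_thresholds()].
#' @param core_boundary Ring(s) delimiting the analyzable core region.
#' @return Named numeric: `intra_tumoral`, `peri_tumoral`, `stromal` (mm^2).
#' @export
compartment_areas <- function(clusters, thresholds = zone_thresholds(),
                              core_boundary) {
  stopifnot(inherits(clusters, "tumor_clusters"),
            inherits(thresholds, "zone_thresholds"))
  if (length(clusters$rings) == 0L) {
    abort("Empty cluster set: compartments undefined.",
          class = "immunozone_error_no_tumor")
  }
  clip_area <- function(rings) {
    rings_area(polyclip::polyclip(rings, core_boundary, op = "intersection",
                                  fillA = "nonzero", fillB = "nonzero"))
  }
  grow <- function(delta) {
    polyclip::polyoffset(clusters$rings, delta, jointype = "round")
  }
  core_area <- rings_area(core_boundary)
  a_intra <- clip_area(grow(thresholds$intra_max))
  a_peri_tot <- clip_area(grow(thresholds$peri_max))
  c(intra_tumoral = a_intra,
    peri_tumoral = a_peri_tot - a_intra,
    stromal = core_area - a_peri_tot) / UM2_PER_MM2
}

#' Per-case immune profiles for a cohort of cores
#'
#' Runs the full spatial stage for every core — cluster reconstruction,
#' compartment assignment, counting — and aggregates to per-case metrics:
#' compartment densities (counts normalized to tumor-cluster area, averaged
#' across replicate cores), the CD8+:FOXP3+ ratio, and the PD-L1 CPS with
#' its >= 1 positivity call.  Cores with zero retained tumor area are
#' dropped with a warning (density denominator undefined).
#'
#' @param cells Cell table for the whole cohort (`core_id`, `case_id`,
#'   `x_um`, `y_um`, `cell_class`, `pdl1_positive`, `cps_class`, `viable`).
#' @param exclusions Optional named list: `core_id` -> list of exclusion
#'   rings.
#' @param thresholds [zone_thresholds()].
#' @param merge_radius,min_cells Cluster-reconstruction parameters, see
#'   [build_tumor_clusters()].
#' @param cps_threshold Case-level CPS positivity cutoff (default 1).
#' @return An `immune_profiles` object: `$densities` (case x phenotype x
#'   zone, cells/mm^2), `$scores` (per-case ratio, CPS, positivity),
#'   `$cores` (per-core detail) and `$dropped_cores`.
#' @export
profile_cases <- function(cells, exclusions = NULL,
                          thresholds = zone_thresholds(),
                          merge_radius = 15, min_cells = 5,
                          cps_threshold = 1) {
  stopifnot(is.data.frame(cells))
  req <- c("core_id", "case_id", "x_um", "y_um", "cell_class",
           "pdl1_positive", "cps_class", "viable")
  miss <- setdiff(req, names(cells))
  if (length(miss) > 0L) {
    abort(paste0("Cell table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "immunozone_error_input")
  }

  per_core <- cells |>
    group_by(.data$case_id, .data$core_id) |>
    group_map(function(df, key) {
      excl <- if (!is.null(exclusions)) exclusions[[key$core_id]] else NULL
      cl <- build_tumor_clusters(cbind(core_id = key$core_id, df),
                                 merge_radius = merge_radius,
                                 min_cells = min_cells, exclusions = excl)
      area <- cluster_area(cl)
      if (area <= 0) {
        warn(paste0("Core ", key$core_id,
                    ": zero tumor-cluster area; core dropped."),
             class = "immunozone_warn_dropped_core")
        return(list(key = key, dropped = TRUE))
      }
      counts <- zone_counts(df, cl, thresholds, exclusions = excl)
      list(key = key, dropped = FALSE, area = area, counts = counts,
           cps = cps(df),
           cd8 = sum(df$cell_class == "CD8"),
           foxp3 = sum(df$cell_class == "FOXP3"))
    })

  dropped <- purrr::map_chr(purrr::keep(per_core, "dropped"),
                            ~ .x$key$core_id)
  per_core <- purrr::discard(per_core, "dropped")
  if (length(per_core) == 0L) {
    abort("No evaluable core (all cores lack tumor-cluster area).",
          class = "immunozone_error_no_tumor")
  }

  cores <- purrr::map_dfr(per_core, function(p) {
    p$counts |>
      mutate(case_id = p$key$case_id, core_id = p$key$core_id,
             area_mm2 = p$area, density = cell_density(.data$n, p$area),
             .before = 1L)
  })
  core_scores <- purrr::map_dfr(per_core, function(p) {
    tibble(case_id = p$key$case_id, core_id = p$key$core_id,
           cps = p$cps, cd8 = p$cd8, foxp3 = p$foxp3)
  })

  densities <- cores |>
    group_by(.data$case_id, .data$phenotype, .data$zone) |>
    summarise(density = aggregate_replicates(.data$density),
              .groups = "drop")
  scores <- core_scores |>
    group_by(.data$case_id) |>
    summarise(
      n_cores = dplyr::n(),
      cd8_foxp3_ratio = cd8_foxp3_ratio(.data$cd8, .data$foxp3),
      cps = aggregate_replicates(.data$cps),
      .groups = "drop"
    ) |>
    mutate(cps_positive = !is.na(.data$cps) & .data$cps >= cps_threshold)

  structure(list(densities = densities, scores = scores, cores = cores,
                 dropped_cores = dropped),
            class = "immune_profiles")
}

#' @export
print.immune_profiles <- function(x, ...) {
  cat("<immune_profiles> ", dplyr::n_distinct(x$scores$case_id), " cases, ",
      dplyr::n_distinct(x$cores$core_id), " evaluable cores",
      if (length(x$dropped_cores) > 0L)
        paste0(" (", length(x$dropped_cores), " dropped)"), "\n", sep = "")
  print(x$scores, n = 5)
  invisible(x)
}
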