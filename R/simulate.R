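# Synthetic tissue-core and cohort simulator.  Tumor nests are unions of
# discs around Gaussian-scattered tumor cells (reproducing irregular
# epithelial cluster morphology without image data); immune cells are placed
# by homogeneous Poisson point processes within each true compartment at
# configured areal intensities, so compartment densities are recoverable by
# construction.  PD-L1 positivity is a per-class Bernoulli draw; molecular
# annotations are built to be rule-consistent with the intended subgroup;
# survival times are exponential with administrative censoring.

#' Default per-compartment immune intensities (cells/mm^2)
#'
#' The HR/MMR-intact profile.  The intra-tumoral CD8+ and FOXP3+ values are
#' cohort-level group means reported for resected PDAC (40.5 and 13.6
#' cells/mm^2); peri-tumoral and stromal values, and the CD68+ profile, are
#' plausible values for a stroma-rich, immune-cold carcinoma chosen once
#' and fixed (the compared groups share them, matching the absence of
#' peri-tumoral/stromal differences).
#'
#' @return Tibble with columns `phenotype`, `zone`, `intensity`.
#' @export
default_immune_intensity <- function() {
  tibble(
    phenotype = rep(PHENOTYPES, each = 3L),
    zone = rep(ZONES, times = 3L),
    intensity = c(40.5, 60, 80,    # CD8
                  13.6, 20, 25,    # FOXP3
                  35, 45, 55)      # CD68
  )
}

#' Per-subgroup intensity profiles
#'
#' HR-d differs from HR/MMR-intact only intra-tumorally (CD8+ 131.1 vs 40.5
#' cells/mm^2, FOXP3+ 25.5 vs 13.6 cells/mm^2); the single MMR-d reference
#' profile is given a strongly T-cell-inflamed intra-tumoral compartment.
#'
#' @return Named list of intensity tibbles (see
#'   [default_immune_intensity()]), one per subgroup.
#' @export
default_group_intensities <- function() {
  base <- default_immune_intensity()
  hrd <- base
  hrd$intensity[hrd$phenotype == "CD8" & hrd$zone == "intra_tumoral"] <- 131.1
  hrd$intensity[hrd$phenotype == "FOXP3" & hrd$zone == "intra_tumoral"] <- 25.5
  mmrd <- base
  mmrd$intensity[mmrd$phenotype == "CD8" & mmrd$zone == "intra_tumoral"] <- 320
  mmrd$intensity[mmrd$phenotype == "FOXP3" & mmrd$zone == "intra_tumoral"] <- 25
  list(HR_MMR_intact = base, HR_d = hrd, MMR_d = mmrd)
}

#' Configuration for one synthetic tissue core
#'
#' @param core_diameter Core diameter in um (default 1500, a 1.5-mm TMA
#'   core).
#' @param n_clusters Number of tumor nests.
#' @param cluster_radius_mean,cluster_radius_sd Mean/SD of the per-nest
#'   scatter radius (um); tumor cells are Gaussian-scattered (SD = radius/2)
#'   and truncated at the radius.
#' @param n_tumor_cells_per_cluster Tumor cells per nest.
#' @param merge_radius Disc radius (um) defining the true nest geometry —
#'   matched by default to the reconstruction radius so the analyzed
#'   geometry equals the generating geometry.
#' @param min_cells Minimum tumor-cell support per retained nest component.
#' @param immune_intensity Tibble `phenotype`, `zone`, `intensity`
#'   (cells/mm^2 of the compartment); see [default_immune_intensity()].
#' @param pdl1_fraction Named per-class PD-L1 positivity probabilities for
#'   `tumor_cell`, `lymphocyte`, `macrophage`.
#' @param thresholds [zone_thresholds()] defining the true compartments.
#' @param seed Optional integer seed (set per call for reproducibility).
#' @return Validated `core_sim_config` list.
#' @export
core_sim_config <- function(core_diameter = 1500, n_clusters = 4,
                            cluster_radius_mean = 180, cluster_radius_sd = 30,
                            n_tumor_cells_per_cluster = 350,
                            merge_radius = 15, min_cells = 5,
                            immune_intensity = default_immune_intensity(),
                            pdl1_fraction = c(tumor_cell = 2e-4,
                                              lymphocyte = 2e-4,
                                              macrophage = 2e-4),
                            thresholds = zone_thresholds(), seed = NULL) {
  cfg <- list(core_diameter = core_diameter, n_clusters = n_clusters,
              cluster_radius_mean = cluster_radius_mean,
              cluster_radius_sd = cluster_radius_sd,
              n_tumor_cells_per_cluster = n_tumor_cells_per_cluster,
              merge_radius = merge_radius, min_cells = min_cells,
              immune_intensity = immune_intensity,
              pdl1_fraction = pdl1_fraction, thresholds = thresholds,
              seed = seed)
  if (!(core_diameter > 0)) {
    abort("core_diameter must be positive.", class = "immunozone_error_config")
  }
  if (any(immune_intensity$intensity < 0)) {
    abort("Immune intensities must be >= 0.", class = "immunozone_error_config")
  }
  if (any(pdl1_fraction < 0 | pdl1_fraction > 1)) {
    abort("PD-L1 fractions must lie in [0, 1].",
          class = "immunozone_error_config")
  }
  max_reach <- cluster_radius_mean + 3 * cluster_radius_sd + merge_radius
  if (n_clusters >= 1 && max_reach >= core_diameter / 2) {
    abort("Cluster geometry cannot fit inside the core disc.",
          class = "immunozone_error_config")
  }
  structure(cfg, class = "core_sim_config")
}

#' Simulate one tissue core
#'
#' @param config A [core_sim_config()].
#' @param core_id,case_id Identifiers stamped on the emitted records.
#' @return List with `cells` (a cell-record tibble), `clusters` (the true
#'   `tumor_clusters` geometry) and `truth` (true compartment areas in
#'   mm^2, the configured intensities, and bookkeeping) — the ground truth
#'   for parameter-recovery tests.
#' @examples
#' sim <- simulate_core(core_sim_config(seed = 1))
#' dplyr::count(sim$cells, cell_class)
#' @export
simulate_core <- function(config, core_id = "core_1", case_id = "case_1") {
  stopifnot(inherits(config, "core_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  R <- config$core_diameter / 2

  # Tumor nests: Gaussian-scattered cells truncated at the nest radius.
  tumor_xy <- purrr::map_dfr(seq_len(config$n_clusters), function(k) {
    rad <- max(rnorm(1, config$cluster_radius_mean, config$cluster_radius_sd),
               config$merge_radius * 2)
    max_c <- R - rad - config$merge_radius
    if (max_c <= 0) {
      abort("Cluster geometry cannot fit inside the core disc.",
            class = "immunozone_error_config")
    }
    th <- runif(1, 0, 2 * pi)
    rc <- max_c * sqrt(runif(1))
    cx <- rc * cos(th); cy <- rc * sin(th)
    n <- config$n_tumor_cells_per_cluster
    pts <- matrix(numeric(0), ncol = 2)
    while (nrow(pts) < n) {
      cand <- cbind(rnorm(2 * n, 0, rad / 2), rnorm(2 * n, 0, rad / 2))
      keep <- sqrt(rowSums(cand^2)) <= rad
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    tibble(x_um = cx + pts[seq_len(n), 1], y_um = cy + pts[seq_len(n), 2])
  })

  tumor <- tibble(core_id = core_id, case_id = case_id,
                  x_um = tumor_xy$x_um, y_um = tumor_xy$y_um,
                  cell_class = "tumor")
  clusters <- build_tumor_clusters(tumor, merge_radius = config$merge_radius,
                                   min_cells = config$min_cells)
  core_ring <- list(disc_ring(0, 0, R, n = 256L))
  areas <- pmax(compartment_areas(clusters, config$thresholds, core_ring), 0)

  # Immune placement: one uniform pool over the core disc, classified once
  # per batch, drawn down per compartment (rejection sampling against the
  # true geometry).
  want <- config$immune_intensity |>
    mutate(n = rpois(dplyr::n(), .data$intensity * areas[.data$zone]))
  need_by_zone <- tapply(want$n, want$zone, sum)[ZONES]
  need_by_zone[is.na(need_by_zone)] <- 0

  pool <- list(x = numeric(), y = numeric(), zone = character())
  frac <- pmax(areas / sum(areas), 1e-3)
  tries <- 0L
  while (any(need_by_zone > 0 &
             vapply(ZONES, function(z) sum(pool$zone == z), numeric(1)) <
               need_by_zone)) {
    m <- as.integer(max(2 * max(need_by_zone / frac), 500))
    th <- runif(m, 0, 2 * pi); rr <- R * sqrt(runif(m))
    px <- rr * cos(th); py <- rr * sin(th)
    z <- as.character(assign_zone(signed_distance(clusters, px, py),
                                  config$thresholds))
    pool <- list(x = c(pool$x, px), y = c(pool$y, py),
                 zone = c(pool$zone, z))
    tries <- tries + 1L
    if (tries > 100L) {
      abort("Rejection sampling failed: a compartment with demanded cells has (near-)zero area.",
            class = "immunozone_error_config")
    }
  }

  taken <- setNames(rep(0L, 3L), ZONES)
  imm <- purrr::pmap_dfr(want, function(phenotype, zone, intensity, n) {
    zone <- as.character(zone)
    if (n == 0L) return(tibble())
    idx <- which(pool$zone == zone)[taken[zone] + seq_len(n)]
    taken[zone] <<- taken[zone] + n
    tibble(core_id = core_id, case_id = case_id,
           x_um = pool$x[idx], y_um = pool$y[idx], cell_class = phenotype)
  })

  cells <- bind_rows(tumor, imm) |>
    mutate(
      cps_class = dplyr::case_match(.data$cell_class,
                                    "tumor" ~ "tumor_cell",
                                    c("CD8", "FOXP3") ~ "lymphocyte",
                                    "CD68" ~ "macrophage",
                                    .default = "other"),
      pdl1_positive = rbinom(dplyr::n(), 1L,
                             unname(config$pdl1_fraction[.data$cps_class])) == 1L,
      viable = TRUE
    ) |>
    select(dplyr::all_of(CELL_TABLE_COLS))

  truth <- list(core_id = core_id, case_id = case_id, areas_mm2 = areas,
                intensity = config$immune_intensity,
                cluster_area_mm2 = cluster_area(clusters),
                n_tumor_cells = nrow(tumor))
  list(cells = cells, clusters = clusters, truth = truth)
}

# Deterministic per-(case, core) substream seed derived from the root seed
# by Lehmer-style mixing; reproducible independent of generation order.
substream_seed <- function(seed, i, j = 0L) {
  m <- 2147483647
  h <- as.double(seed %% m)
  h <- (h * 48271 + i) %% m
  h <- (h * 48271 + j) %% m
  as.integer(h)
}

#' Configuration for a synthetic cohort
#'
#' @param n_cases_per_group Named counts per subgroup (defaults mirror a
#'   192-case resected-PDAC cohort: 166 HR/MMR-intact, 25 HR-d, 1 MMR-d).
#' @param cores_per_case Replicate tumor cores per case (default 3).
#' @param group_intensity Named list subgroup -> intensity tibble
#'   ([default_group_intensities()]).
#' @param pdl1_fraction Named list subgroup -> per-class PD-L1 positivity
#'   base probabilities.
#' @param survival_median Named true median overall survival per subgroup
#'   (months); defaults 19.9 (intact) and 29.1 (HR-d).
#' @param censor_horizon Administrative censoring horizon (months,
#'   default 60).
#' @param case_dispersion SD (log scale) of the per-case, per-phenotype
#'   lognormal intensity multiplier producing the heavy-tailed between-case
#'   spread seen in real cohorts (default 0.8).
#' @param pdl1_dispersion SD (log scale) of the per-case PD-L1 propensity
#'   multiplier (default 1.5).
#' @param stage_late_prob Named probability of late-stage (III/IV) disease
#'   per subgroup (defaults 7/166, 13/25, 0).
#' @param core Base [core_sim_config()] shared by all cores.
#' @param seed Root integer seed; per-core substreams are derived from it.
#' @return Validated `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_cases_per_group = c(HR_MMR_intact = 166,
                                                    HR_d = 25, MMR_d = 1),
                              cores_per_case = 3,
                              group_intensity = default_group_intensities(),
                              pdl1_fraction = list(
                                HR_MMR_intact = c(tumor_cell = 2e-4,
                                                  lymphocyte = 2e-4,
                                                  macrophage = 2e-4),
                                HR_d = c(tumor_cell = 1.5e-3,
                                         lymphocyte = 1.5e-3,
                                         macrophage = 1.5e-3),
                                MMR_d = c(tumor_cell = 2e-2,
                                          lymphocyte = 2e-2,
                                          macrophage = 2e-2)),
                              survival_median = c(HR_MMR_intact = 19.9,
                                                  HR_d = 29.1, MMR_d = 29.1),
                              censor_horizon = 60,
                              case_dispersion = 0.8, pdl1_dispersion = 1.5,
                              stage_late_prob = c(HR_MMR_intact = 7 / 166,
                                                  HR_d = 13 / 25, MMR_d = 0),
                              core = core_sim_config(), seed = 1L) {
  bad <- setdiff(names(n_cases_per_group), SUBGROUPS)
  if (length(bad) > 0L) {
    abort(paste0("Unrecognized subgroup(s): ", paste(bad, collapse = ", ")),
          class = "immunozone_error_config")
  }
  if (any(n_cases_per_group < 1)) {
    abort("Each requested subgroup needs at least one case.",
          class = "immunozone_error_config")
  }
  if (any(survival_median[names(n_cases_per_group)] <= 0, na.rm = TRUE)) {
    abort("Survival medians must be positive.",
          class = "immunozone_error_config")
  }
  structure(list(n_cases_per_group = n_cases_per_group,
                 cores_per_case = cores_per_case,
                 group_intensity = group_intensity,
                 pdl1_fraction = pdl1_fraction,
                 survival_median = survival_median,
                 censor_horizon = censor_horizon,
                 case_dispersion = case_dispersion,
                 pdl1_dispersion = pdl1_dispersion,
                 stage_late_prob = stage_late_prob,
                 core = core, seed = seed),
            class = "cohort_sim_config")
}

# Build a molecular annotation row guaranteed to classify into `label`.
simulate_annotation <- function(case_id, label) {
  retained <- rep("retained", 4L)
  row <- tibble(case_id = case_id, germline_hr_gene = NA_character_,
                somatic_hr_inactivation = FALSE, hrdetect = NA_real_,
                low_cellularity = FALSE, germline_mmr_gene = NA_character_,
                mmr_ihc_mlh1 = retained[1], mmr_ihc_msh2 = retained[2],
                mmr_ihc_msh6 = retained[3], mmr_ihc_pms2 = retained[4],
                msisensor = round(runif(1, 0, 3), 2))
  u <- runif(1)
  if (label == "HR_d") {
    if (u < 0.50) {
      row$germline_hr_gene <- "BRCA2"; row$hrdetect <- 0.999
      row$somatic_hr_inactivation <- TRUE
    } else if (u < 0.62) {
      row$germline_hr_gene <- "BRCA1"; row$hrdetect <- 0.999
      row$somatic_hr_inactivation <- TRUE
    } else if (u < 0.72) {
      row$germline_hr_gene <- sample(c("BRCA2", "PALB2"), 1L)
    } else if (u < 0.80) {
      row$hrdetect <- 0.999; row$somatic_hr_inactivation <- TRUE
    } else if (u < 0.86) {
      row$germline_hr_gene <- "PALB2"; row$hrdetect <- 0.742
      row$low_cellularity <- TRUE; row$somatic_hr_inactivation <- TRUE
    } else {
      row$germline_hr_gene <- "BRCA2"
    }
  } else if (label == "MMR_d") {
    if (u < 0.6) {
      lost <- sample(c("msh2_msh6", "mlh1_pms2", "msh6"), 1L)
      if (lost == "msh2_msh6") {
        row$mmr_ihc_msh2 <- "lost"; row$mmr_ihc_msh6 <- "lost"
        row$germline_mmr_gene <- "MSH2"
      } else if (lost == "mlh1_pms2") {
        row$mmr_ihc_mlh1 <- "lost"; row$mmr_ihc_pms2 <- "lost"
      } else {
        row$mmr_ihc_msh6 <- "lost"
      }
    } else {
      row[paste0("mmr_ihc_", tolower(MMR_GENES))] <- "not_assessed"
      row$msisensor <- round(20 + runif(1, 0, 15), 2)
    }
  } else if (label == "HR_MMR_intact") {
    if (u < 0.05) {
      # germline carrier failing the HRDetect threshold stays intact
      row$germline_hr_gene <- "BRCA2"
      row$hrdetect <- round(runif(1, 0.05, 0.5), 3)
    } else if (u < 0.30) {
      row$hrdetect <- round(runif(1, 0, 0.5), 3)
    }
  } else {
    abort(paste0("Unrecognized subgroup: ", label),
          class = "immunozone_error_config")
  }
  row
}

#' Simulate a full cohort
#'
#' Generates replicate cores per case (case-level lognormal intensity
#' multipliers shared across a case's cores), rule-consistent molecular
#' annotations, a clinical table with exponential survival times under
#' administrative censoring, and the ground truth.
#'
#' @param config A [cohort_sim_config()].
#' @return List with `cells`, `annotations`, `clinical` (case_id, subgroup,
#'   stage, time_months, event), and `truth` (`$cases`, `$cores`).
#' @examples
#' cfg <- cohort_sim_config(
#'   n_cases_per_group = c(HR_d = 2, HR_MMR_intact = 3),
#'   cores_per_case = 1,
#'   core = core_sim_config(core_diameter = 700, n_clusters = 2,
#'                          cluster_radius_mean = 90, cluster_radius_sd = 10,
#'                          n_tumor_cells_per_cluster = 80),
#'   seed = 42)
#' sim <- simulate_cohort(cfg)
#' nrow(sim$clinical)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  groups <- names(config$n_cases_per_group)
  plan <- tibble(
    subgroup = rep(groups, times = config$n_cases_per_group),
  ) |>
    mutate(case_idx = dplyr::row_number(),
           case_id = sprintf("%s_%03d", .data$subgroup, dplyr::row_number()))

  cases <- purrr::pmap(plan, function(subgroup, case_idx, case_id) {
    set.seed(substream_seed(config$seed, case_idx, 0L))
    base_int <- config$group_intensity[[subgroup]]
    mult <- setNames(exp(rnorm(length(PHENOTYPES), 0, config$case_dispersion)),
                     PHENOTYPES)
    case_int <- mutate(base_int,
                       intensity = .data$intensity * mult[.data$phenotype])
    pdl1 <- pmin(config$pdl1_fraction[[subgroup]] *
                   exp(rnorm(1, 0, config$pdl1_dispersion)), 1)
    ann <- simulate_annotation(case_id, subgroup)
    med <- config$survival_median[[subgroup]]
    t_true <- rexp(1, rate = log(2) / med)
    stage_late <- runif(1) < config$stage_late_prob[[subgroup]]

    cores <- purrr::map(seq_len(config$cores_per_case), function(j) {
      core_cfg <- config$core
      core_cfg$immune_intensity <- case_int
      core_cfg$pdl1_fraction <- pdl1
      core_cfg$seed <- substream_seed(config$seed, case_idx, j)
      simulate_core(core_cfg, core_id = sprintf("%s_c%d", case_id, j),
                    case_id = case_id)
    })

    list(
      cells = purrr::map_dfr(cores, "cells"),
      annotation = ann,
      clinical = tibble(
        case_id = case_id, subgroup = subgroup,
        stage = if (stage_late) "late" else "early",
        time_months = min(t_true, config$censor_horizon),
        event = t_true <= config$censor_horizon
      ),
      truth_cores = purrr::map_dfr(cores, function(cr) {
        mutate(cr$truth$intensity,
               case_id = cr$truth$case_id, core_id = cr$truth$core_id,
               area_mm2 = unname(cr$truth$areas_mm2[.data$zone]),
               cluster_area_mm2 = cr$truth$cluster_area_mm2,
               .before = 1L)
      }),
      truth_case = tibble(case_id = case_id, subgroup = subgroup,
                          survival_median = med,
                          intensity_multiplier = list(mult))
    )
  })

  list(
    cells = purrr::map_dfr(cases, "cells"),
    annotations = purrr::map_dfr(cases, "annotation"),
    clinical = purrr::map_dfr(cases, "clinical"),
    truth = list(cores = purrr::map_dfr(cases, "truth_cores"),
                 cases = purrr::map_dfr(cases, "truth_case"))
  )
}
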