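# Compartment assignment: every immune cell is banded by its signed distance
# to the tumor-cluster perimeter into the intra-tumoral (<= 10 um, including
# cells inside clusters), peri-tumoral (10-50 um) or stromal (> 50 um)
# compartment.

ZONES <- c("intra_tumoral", "peri_tumoral", "stromal")
PHENOTYPES <- c("CD8", "FOXP3", "CD68")
CELL_CLASSES <- c("tumor", "CD8", "FOXP3", "CD68", "other")
CPS_CLASSES <- c("tumor_cell", "lymphocyte", "macrophage", "other")

#' Distance thresholds for compartment banding
#'
#' @param intra_max Outer limit of the intra-tumoral band in um (default 10).
#' @param peri_max Outer limit of the peri-tumoral band in um (default 50).
#' @return A validated `zone_thresholds` list.
#' @export
zone_thresholds <- function(intra_max = 10, peri_max = 50) {
  if (!is.numeric(intra_max) || !is.numeric(peri_max) ||
      length(intra_max) != 1L || length(peri_max) != 1L ||
      !(intra_max > 0) || !(peri_max > intra_max)) {
    abort("Need 0 < intra_max < peri_max.", class = "immunozone_error_config")
  }
  structure(list(intra_max = intra_max, peri_max = peri_max),
            class = "zone_thresholds")
}

#' Band a signed distance into a spatial compartment
#'
#' Cells within `intra_max` of the cluster perimeter (including cells inside
#' a cluster, which carry negative distances) are intra-tumoral; cells
#' between `intra_max` and `peri_max` are peri-tumoral; cells farther than
#' `peri_max` are stromal.  Band boundaries are closed on the inner side.
#'
#' @param distance Signed distance(s) in um (negative = inside a cluster).
#' @param thresholds A [zone_thresholds()] object.
#' @return Factor with levels `intra_tumoral`, `peri_tumoral`, `stromal`.
#' @examples
#' assign_zone(c(-5, 30, 60))
#' @export
assign_zone <- function(distance, thresholds = zone_thresholds()) {
  stopifnot(inherits(thresholds, "zone_thresholds"))
  if (any(!is.finite(distance))) {
    abort("Distances must be finite.", class = "immunozone_error_input")
  }
  z <- ifelse(distance <= thresholds$intra_max, ZONES[1L],
              ifelse(distance <= thresholds$peri_max, ZONES[2L], ZONES[3L]))
  factor(z, levels = ZONES)
}

#' Assign every immune cell of a core to a compartment
#'
#' Computes the signed distance of each non-tumor cell to the tumor-cluster
#' perimeter and bands it with [assign_zone()].  Cells falling inside
#' exclusion regions are dropped.  If the core has no retained tumor
#' cluster, zones cannot be defined: all cells get `NA` zones and a warning
#' is raised so the core can be dropped upstream.
#'
#' @param cells Cell records for one core (columns `x_um`, `y_um`,
#'   `cell_class`, ...).
#' @param clusters `tumor_clusters` for the same core.
#' @param thresholds [zone_thresholds()].
#' @param exclusions Optional exclusion rings; cells inside them are omitted.
#' @return The non-tumor rows of `cells` (minus excluded cells) with
#'   `distance_um` and `zone` columns appended.
#' @export
zone_cells <- function(cells, clusters, thresholds = zone_thresholds(),
                       exclusions = NULL) {
  stopifnot(is.data.frame(cells), inherits(clusters, "tumor_clusters"))
  imm <- as_tibble(cells[cells$cell_class != "tumor", , drop = FALSE])
  if (!is.null(exclusions) && length(exclusions) > 0L && nrow(imm) > 0L) {
    imm <- imm[!points_in_rings(imm$x_um, imm$y_um, exclusions), , drop = FALSE]
  }
  if (nrow(imm) == 0L) {
    imm$distance_um <- numeric()
    imm$zone <- factor(character(), levels = ZONES)
    return(imm)
  }
  if (length(clusters$rings) == 0L) {
    warn(paste0("Core ", clusters$core_id,
                ": no tumor clusters; compartments undefined."),
         class = "immunozone_warn_no_tumor")
    imm$distance_um <- NA_real_
    imm$zone <- factor(NA_character_, levels = ZONES)
    return(imm)
  }
  imm$distance_um <- signed_distance(clusters, imm$x_um, imm$y_um)
  imm$zone <- assign_zone(imm$distance_um, thresholds)
  imm
}

#' Per-phenotype, per-compartment cell counts for a core
#'
#' @inheritParams zone_cells
#' @param phenotypes Cell classes to tabulate (default CD8, FOXP3, CD68).
#' @return A tibble with one row per (phenotype, zone) — the complete grid,
#'   zero-filled — and an `n` count column.  Cores without tumor clusters
#'   return `NA` counts (unassignable).
#' @export
zone_counts <- function(cells, clusters, thresholds = zone_thresholds(),
                        exclusions = NULL, phenotypes = PHENOTYPES) {
  zc <- zone_cells(cells, clusters, thresholds, exclusions)
  grid <- tidyr::expand_grid(
    phenotype = factor(phenotypes, levels = phenotypes),
    zone = factor(ZONES, levels = ZONES)
  )
  if (nrow(zc) > 0L && all(is.na(zc$zone))) {
    grid$n <- NA_integer_
    return(grid)
  }
  tab <- zc |>
    filter(.data$cell_class %in% phenotypes) |>
    count(phenotype = factor(.data$cell_class, levels = phenotypes),
          zone = .data$zone)
  grid |>
    left_join(tab, by = c("phenotype", "zone")) |>
    mutate(n = as.integer(tidyr::replace_na(.data$n, 0L)))
}
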