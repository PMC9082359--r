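# Tumor-cluster geometry: disc-union reconstruction of tumor nests from
# labeled tumor-cell coordinates, cluster areas, and signed distances.
# All coordinates are planar micrometers; areas are reported in mm^2
# (1 mm^2 = 1e6 um^2).

UM2_PER_MM2 <- 1e6

#' Regular polygon approximating a disc
#'
#' @param cx,cy Centre coordinates (um).
#' @param r Radius (um).
#' @param n Number of vertices (default 64; area error below 0.2%).
#' @return A ring: list with numeric `x` and `y`, counter-clockwise.
#' @keywords internal
disc_ring <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

# Signed shoelace area of one ring (um^2): positive counter-clockwise.
ring_area <- function(ring) {
  x <- ring$x
  y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

rings_area <- function(rings) {
  if (length(rings) == 0L) return(0)
  sum(vapply(rings, ring_area, numeric(1)))
}

# Flatten a list of rings into the vectors the compiled kernels expect.
flatten_rings <- function(rings) {
  lens <- vapply(rings, function(r) length(r$x), integer(1))
  list(
    vx = unlist(lapply(rings, `[[`, "x"), use.names = FALSE),
    vy = unlist(lapply(rings, `[[`, "y"), use.names = FALSE),
    start = as.integer(cumsum(c(0L, lens[-length(lens)]))),
    len = as.integer(lens)
  )
}

points_in_rings <- function(x, y, rings) {
  if (length(rings) == 0L) return(rep(FALSE, length(x)))
  f <- flatten_rings(rings)
  points_in_rings_cpp(x, y, f$vx, f$vy, f$start, f$len)
}

#' Build tumor clusters from labeled tumor cells
#'
#' Reconstructs tumor-cluster geometry for one tissue core as the union of
#' discs of radius `merge_radius` centred on every tumor cell.  Connected
#' components of that union are the clusters; components supported by fewer
#' than `min_cells` tumor cells are discarded as isolated cells or debris.
#' Exclusion regions (necrosis, vessels, acinar or islet tissue) are
#' subtracted from the area denominator but the pre-exclusion outline is kept
#' for distance banding, so a necrotic hole inside a nest does not relabel
#' adjacent cells as stromal.
#'
#' @param cells Data frame of cell records for a single core with at least
#'   `x_um`, `y_um` and `cell_class` columns; only rows with
#'   `cell_class == "tumor"` contribute geometry.
#' @param merge_radius Disc radius in um (default 15); tumor cells closer
#'   than `2 * merge_radius` end up in the same cluster.
#' @param min_cells Minimum tumor cells per retained cluster (default 5).
#' @param exclusions Optional list of exclusion rings (each a list with `x`,
#'   `y` in um), e.g. from [read_polygons_geojson()].
#' @param n_vertices Vertices per disc polygon (default 64).
#' @return A `tumor_clusters` object: rings of the retained cluster polygons,
#'   per-cluster tumor-cell counts, and `total_area_mm2` (exclusions
#'   subtracted).  No tumor cells yields an empty set with zero area.
#' @examples
#' cells <- tibble::tibble(
#'   core_id = "c1", x_um = c(0, 10, 20), y_um = 0, cell_class = "tumor"
#' )
#' cl <- build_tumor_clusters(cells, merge_radius = 15, min_cells = 1)
#' cl$n_clusters
#' cluster_area(cl)
#' @export
build_tumor_clusters <- function(cells, merge_radius = 15, min_cells = 5,
                                 exclusions = NULL, n_vertices = 64L) {
  stopifnot(is.data.frame(cells))
  if (!all(c("x_um", "y_um", "cell_class") %in% names(cells))) {
    abort("`cells` must have columns x_um, y_um, cell_class.",
          class = "immunozone_error_input")
  }
  core_id <- if ("core_id" %in% names(cells)) unique(cells$core_id) else NA_character_
  if (length(core_id) > 1L) {
    abort("`cells` must contain a single core_id; got several.",
          class = "immunozone_error_input")
  }
  if (!is.numeric(merge_radius) || length(merge_radius) != 1L || merge_radius <= 0) {
    abort("`merge_radius` must be a single positive number (um).",
          class = "immunozone_error_input")
  }
  tum <- cells[cells$cell_class == "tumor", , drop = FALSE]
  if (nrow(tum) > 0L && any(!is.finite(tum$x_um) | !is.finite(tum$y_um))) {
    bad <- which(!is.finite(tum$x_um) | !is.finite(tum$y_um))[1L]
    abort(paste0("Non-finite tumor-cell coordinate (tumor row ", bad, ")."),
          class = "immunozone_error_input")
  }

  empty <- structure(
    list(core_id = core_id, rings = list(), ring_cluster = integer(),
         ring_is_hole = logical(), n_clusters = 0L,
         cells_per_cluster = integer(), total_area_mm2 = 0,
         exclusions_applied = !is.null(exclusions),
         merge_radius = merge_radius, min_cells = min_cells),
    class = "tumor_clusters"
  )
  if (nrow(tum) == 0L) return(empty)

  discs <- purrr::map2(tum$x_um, tum$y_um, disc_ring,
                       r = merge_radius, n = as.integer(n_vertices))
  rings <- polyclip::polyclip(discs, discs, op = "union",
                              fillA = "nonzero", fillB = "nonzero")
  areas <- vapply(rings, ring_area, numeric(1))
  outer <- which(areas > 0)
  holes <- which(areas <= 0)

  # Tumor cells sit inside exactly one outer ring; count support per cluster.
  cluster_of_cell <- rep(NA_integer_, nrow(tum))
  for (k in seq_along(outer)) {
    inside <- points_in_rings(tum$x_um, tum$y_um, rings[outer[k]])
    cluster_of_cell[is.na(cluster_of_cell) & inside] <- k
  }
  # Cells landing exactly on a vertex-approximation edge: assign to nearest
  # outer ring (rare; keeps the support count a partition).
  if (anyNA(cluster_of_cell)) {
    for (i in which(is.na(cluster_of_cell))) {
      d <- vapply(outer, function(o) {
        f <- flatten_rings(rings[o])
        abs(signed_distance_cpp(tum$x_um[i], tum$y_um[i],
                                f$vx, f$vy, f$start, f$len))
      }, numeric(1))
      cluster_of_cell[i] <- which.min(d)
    }
  }
  support <- tabulate(cluster_of_cell, nbins = length(outer))
  keep <- which(support >= min_cells)
  if (length(keep) == 0L) return(empty)

  hole_parent <- vapply(holes, function(h) {
    hit <- which(vapply(outer, function(o) {
      points_in_rings(rings[[h]]$x[1], rings[[h]]$y[1], rings[o])
    }, logical(1)))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))

  kept_rings <- c(rings[outer[keep]], rings[holes[!is.na(hole_parent) & hole_parent %in% keep]])
  ring_cluster <- c(match(keep, keep),
                    match(hole_parent[!is.na(hole_parent) & hole_parent %in% keep], keep))
  ring_is_hole <- c(rep(FALSE, length(keep)),
                    rep(TRUE, sum(!is.na(hole_parent) & hole_parent %in% keep)))

  area_um2 <- rings_area(kept_rings)
  if (!is.null(exclusions) && length(exclusions) > 0L) {
    cut <- polyclip::polyclip(kept_rings, exclusions, op = "intersection",
                              fillA = "nonzero", fillB = "nonzero")
    area_um2 <- area_um2 - rings_area(cut)
  }

  structure(
    list(core_id = core_id, rings = kept_rings,
         ring_cluster = as.integer(ring_cluster),
         ring_is_hole = ring_is_hole, n_clusters = length(keep),
         cells_per_cluster = as.integer(support[keep]),
         total_area_mm2 = max(area_um2, 0) / UM2_PER_MM2,
         exclusions_applied = !is.null(exclusions),
         merge_radius = merge_radius, min_cells = min_cells),
    class = "tumor_clusters"
  )
}

#' @export
print.tumor_clusters <- function(x, ...) {
  cat("<tumor_clusters>", if (!is.na(x$core_id)) paste0("core ", x$core_id), "\n")
  cat("  clusters:", x$n_clusters,
      " total area:", signif(x$total_area_mm2, 4), "mm^2",
      if (x$exclusions_applied) " (exclusions subtracted)", "\n")
  invisible(x)
}

#' Total tumor-cluster area
#'
#' @param clusters A `tumor_clusters` object.
#' @return Total area in mm^2 — the union area of retained clusters with any
#'   exclusion-region overlap subtracted; overlapping discs are never
#'   double-counted.
#' @export
cluster_area <- function(clusters) {
  stopifnot(inherits(clusters, "tumor_clusters"))
  clusters$total_area_mm2
}

#' Signed distance from points to the tumor-cluster boundary
#'
#' Minimum Euclidean distance from each point to the boundary of the retained
#' cluster polygons, negated for points lying inside a cluster.  Distances
#' use the pre-exclusion cluster outline.
#'
#' @param clusters A `tumor_clusters` object with at least one cluster.
#' @param x,y Point coordinates (um).
#' @return Numeric vector of signed distances (um).
#' @export
signed_distance <- function(clusters, x, y) {
  stopifnot(inherits(clusters, "tumor_clusters"))
  if (length(clusters$rings) == 0L) {
    abort("Cluster set is empty: no tumor geometry to measure distances to.",
          class = "immunozone_error_no_tumor")
  }
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(numeric())
  if (any(!is.finite(x) | !is.finite(y))) {
    abort("Non-finite point coordinate.", class = "immunozone_error_input")
  }
  f <- flatten_rings(clusters$rings)
  signed_distance_cpp(as.numeric(x), as.numeric(y), f$vx, f$vy, f$start, f$len)
}

#' Cluster polygons as a tidy tibble
#'
#' @param clusters A `tumor_clusters` object.
#' @return A tibble with columns `cluster`, `ring`, `is_hole`, `x_um`,
#'   `y_um`, one row per polygon vertex — convenient for `ggplot2`.
#' @export
cluster_polygons <- function(clusters) {
  stopifnot(inherits(clusters, "tumor_clusters"))
  if (length(clusters$rings) == 0L) {
    return(tibble(cluster = integer(), ring = integer(),
                  is_hole = logical(), x_um = numeric(), y_um = numeric()))
  }
  purrr::imap_dfr(clusters$rings, function(r, i) {
    tibble(cluster = clusters$ring_cluster[i], ring = i,
           is_hole = clusters$ring_is_hole[i], x_um = r$x, y_um = r$y)
  })
}
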