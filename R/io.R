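# File formats.  Cell tables are comma-separated UTF-8 CSV with "." decimals
# and true/false booleans; coordinates are planar Cartesian micrometers with
# a per-core origin, y-up.  Polygons travel as GeoJSON with coordinates in
# micrometers and a "core_id" feature property.  Annotation, clinical and
# metric tables are TSV.

CELL_TABLE_COLS <- c("core_id", "case_id", "x_um", "y_um", "cell_class",
                     "pdl1_positive", "cps_class", "viable")

#' Read a per-cell coordinate table
#'
#' @param path CSV file with header `core_id,case_id,x_um,y_um,cell_class,`
#'   `pdl1_positive,cps_class,viable`.
#' @return A validated tibble of cell records.  Unknown `cell_class` or
#'   `cps_class` values, non-finite coordinates, missing columns, and tumor
#'   cells whose `cps_class` is not `tumor_cell` are rejected with the
#'   offending row named.
#' @export
read_cell_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  miss <- setdiff(CELL_TABLE_COLS, names(raw))
  if (length(miss) > 0L) {
    abort(paste0("Cell table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "immunozone_error_format")
  }
  as_bool <- function(x) {
    ifelse(tolower(x) %in% c("true", "t", "1"), TRUE,
           ifelse(tolower(x) %in% c("false", "f", "0"), FALSE, NA))
  }
  df <- tibble(
    core_id = raw$core_id, case_id = raw$case_id,
    x_um = suppressWarnings(as.numeric(raw$x_um)),
    y_um = suppressWarnings(as.numeric(raw$y_um)),
    cell_class = raw$cell_class,
    pdl1_positive = as_bool(raw$pdl1_positive),
    cps_class = raw$cps_class,
    viable = as_bool(raw$viable)
  )
  validate_cell_table(df)
}

validate_cell_table <- function(df) {
  miss <- setdiff(CELL_TABLE_COLS, names(df))
  if (length(miss) > 0L) {
    abort(paste0("Cell table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "immunozone_error_format")
  }
  if (nrow(df) == 0L) {
    abort("Cell table is empty.", class = "immunozone_error_format")
  }
  bad_row <- function(cond, what) {
    if (any(cond)) {
      abort(paste0(what, " in row ", which(cond)[1L], "."),
            class = "immunozone_error_format")
    }
  }
  bad_row(!is.finite(df$x_um) | !is.finite(df$y_um),
          "Non-numeric or non-finite coordinate")
  bad_row(!df$cell_class %in% CELL_CLASSES,
          paste0("Unknown cell_class (expected one of ",
                 paste(CELL_CLASSES, collapse = ", "), ")"))
  bad_row(!df$cps_class %in% CPS_CLASSES, "Unknown cps_class")
  bad_row(df$cell_class == "tumor" & df$cps_class != "tumor_cell",
          "Tumor cell with cps_class other than tumor_cell")
  bad_row(is.na(df$pdl1_positive) | is.na(df$viable),
          "Missing pdl1_positive/viable flag")
  as_tibble(df)
}

#' Write a per-cell coordinate table
#'
#' @param cells Cell-record tibble.
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells[, CELL_TABLE_COLS], path)
  invisible(path)
}

#' Read a molecular annotation table
#'
#' @param path TSV with the columns described in [classify_table()].
#' @return Tibble of annotations.
#' @export
read_annotation_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    case_id = readr::col_character(),
                    germline_hr_gene = readr::col_character(),
                    somatic_hr_inactivation = readr::col_logical(),
                    hrdetect = readr::col_double(),
                    low_cellularity = readr::col_logical(),
                    msisensor = readr::col_double(),
                    .default = readr::col_character()
                  ))
}

#' Read a survival table
#'
#' @param path TSV with columns `case_id`, `time_months`, `event`, `group`.
#' @return Tibble with those columns; times must be non-negative.
#' @export
read_survival_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          case_id = readr::col_character(),
                          time_months = readr::col_double(),
                          event = readr::col_logical(),
                          group = readr::col_character()
                        ))
  if (any(df$time_months < 0, na.rm = TRUE)) {
    abort("Negative survival time.", class = "immunozone_error_format")
  }
  df
}

#' Write polygons (clusters or exclusion regions) as GeoJSON
#'
#' Each cluster becomes one `Polygon` feature whose first ring is the outer
#' boundary and subsequent rings are holes; coordinates are micrometers.
#'
#' @param clusters A `tumor_clusters` object, or a bare list of rings
#'   (each ring a list with `x`, `y`).
#' @param path Output path.
#' @param core_id Core identifier stored as a feature property (taken from
#'   the cluster object when available).
#' @export
write_polygons_geojson <- function(clusters, path, core_id = NULL) {
  if (inherits(clusters, "tumor_clusters")) {
    core_id <- core_id %||% clusters$core_id
    feats <- lapply(seq_len(clusters$n_clusters), function(k) {
      idx <- which(clusters$ring_cluster == k)
      idx <- idx[order(clusters$ring_is_hole[idx])]  # outer ring first
      list(
        type = "Feature",
        properties = list(core_id = core_id, cluster = k),
        geometry = list(
          type = "Polygon",
          coordinates = lapply(clusters$rings[idx], ring_coords)
        )
      )
    })
  } else {
    feats <- lapply(seq_along(clusters), function(k) {
      list(
        type = "Feature",
        properties = list(core_id = core_id, cluster = k),
        geometry = list(type = "Polygon",
                        coordinates = list(ring_coords(clusters[[k]])))
      )
    })
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# GeoJSON rings repeat the first vertex to close the ring.
ring_coords <- function(ring) {
  x <- c(ring$x, ring$x[1])
  y <- c(ring$y, ring$y[1])
  lapply(seq_along(x), function(i) c(x[i], y[i]))
}

#' Read polygons from GeoJSON
#'
#' @param path GeoJSON `FeatureCollection` of `Polygon`/`MultiPolygon`
#'   features with micrometre coordinates.
#' @return A list of rings (`x`, `y`, closing vertex removed) with a
#'   `core_id` attribute per ring taken from the feature properties.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    abort("Expected a GeoJSON FeatureCollection.",
          class = "immunozone_error_format")
  }
  rings <- list()
  for (feat in gj$features) {
    cid <- feat$properties$core_id
    geom <- feat$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    abort(paste0("Unsupported geometry type: ", geom$type),
                          class = "immunozone_error_format"))
    for (poly in polys) {
      for (coords in poly) {
        x <- vapply(coords, function(p) as.numeric(p[[1]]), numeric(1))
        y <- vapply(coords, function(p) as.numeric(p[[2]]), numeric(1))
        n <- length(x)
        if (n > 1L && x[1] == x[n] && y[1] == y[n]) {
          x <- x[-n]; y <- y[-n]
        }
        ring <- list(x = x, y = y)
        attr(ring, "core_id") <- cid
        rings[[length(rings) + 1L]] <- ring
      }
    }
  }
  rings
}
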