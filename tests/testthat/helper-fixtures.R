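# Shared fixtures and independent oracles.

# A cell-record tibble from bare coordinates.
make_cells <- function(x, y, cell_class, core_id = "c1", case_id = "k1",
                       pdl1 = FALSE, cps_class = NULL, viable = TRUE) {
  if (is.null(cps_class)) {
    cps_class <- c(tumor = "tumor_cell", CD8 = "lymphocyte",
                   FOXP3 = "lymphocyte", CD68 = "macrophage",
                   other = "other")[cell_class]
  }
  tibble::tibble(core_id = core_id, case_id = case_id, x_um = x, y_um = y,
                 cell_class = cell_class, pdl1_positive = pdl1,
                 cps_class = unname(cps_class), viable = viable)
}

# Small core configurations keeping simulation-heavy tests fast.
small_core_config <- function(seed = NULL, ...) {
  core_sim_config(core_diameter = 700, n_clusters = 2,
                  cluster_radius_mean = 90, cluster_radius_sd = 10,
                  n_tumor_cells_per_cluster = 80, seed = seed, ...)
}

micro_core_config <- function(seed = NULL, ...) {
  core_sim_config(core_diameter = 450, n_clusters = 1,
                  cluster_radius_mean = 70, cluster_radius_sd = 5,
                  n_tumor_cells_per_cluster = 40, seed = seed, ...)
}

# --- independent geometry oracles (pure R, no shared code path) ---------

# Dense resampling of every ring polyline; distance oracle = minimum
# distance to the sampled boundary points.
oracle_boundary_points <- function(clusters, step = 0.25) {
  pts <- lapply(clusters$rings, function(r) {
    x <- c(r$x, r$x[1]); y <- c(r$y, r$y[1])
    out_x <- numeric(); out_y <- numeric()
    for (i in seq_len(length(x) - 1L)) {
      len <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
      out_x <- c(out_x, x[i] + t * (x[i + 1] - x[i]))
      out_y <- c(out_y, y[i] + t * (y[i + 1] - y[i]))
    }
    cbind(out_x, out_y)
  })
  do.call(rbind, pts)
}

oracle_min_distance <- function(clusters, px, py, step = 0.25) {
  b <- oracle_boundary_points(clusters, step)
  vapply(seq_along(px), function(i) {
    sqrt(min((b[, 1] - px[i])^2 + (b[, 2] - py[i])^2))
  }, numeric(1))
}

# Even-odd point-in-polygon over all rings, implemented independently in R.
oracle_inside <- function(clusters, px, py) {
  inside <- rep(FALSE, length(px))
  for (r in clusters$rings) {
    x <- r$x; y <- r$y; n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      cross <- ((y[i] > py) != (y[j] > py)) &
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
      inside <- xor(inside, cross)
      j <- i
    }
  }
  inside
}

oracle_zone <- function(clusters, px, py, intra_max = 10, peri_max = 50) {
  d <- oracle_min_distance(clusters, px, py)
  d[oracle_inside(clusters, px, py)] <- -d[oracle_inside(clusters, px, py)]
  ifelse(d <= intra_max, "intra_tumoral",
         ifelse(d <= peri_max, "peri_tumoral", "stromal"))
}

# --- independent statistics oracles -------------------------------------

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  p <- exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  p_obs <- p[x == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Two-sided exact Wilcoxon p by enumerating all assignments of the pooled
# ranks to group A.
oracle_wilcoxon <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  m <- length(a)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(pooled), m)
  w_all <- apply(combs, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  ew <- m * length(b) / 2
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}
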