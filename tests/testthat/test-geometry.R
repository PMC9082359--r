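test_that("disc-union connectivity merges chains and separates distant cells", {
  chain <- make_cells(c(0, 10, 20), c(0, 0, 0), "tumor")
  cl <- build_tumor_clusters(chain, merge_radius = 15, min_cells = 1)
  expect_equal(cl$n_clusters, 1L)

  apart <- make_cells(c(0, 100), c(0, 0), "tumor")
  cl2 <- build_tumor_clusters(apart, merge_radius = 15, min_cells = 1)
  expect_equal(cl2$n_clusters, 2L)

  # pairwise-distance criterion: cells join iff closer than 2 * radius
  set.seed(11)
  for (rep in 1:5) {
    x <- runif(12, 0, 300); y <- runif(12, 0, 300)
    cl3 <- build_tumor_clusters(make_cells(x, y, "tumor"),
                                merge_radius = 20, min_cells = 1)
    adj <- as.matrix(dist(cbind(x, y))) < 40
    g <- seq_len(12)
    repeat {
      g_new <- vapply(seq_len(12), function(i) min(g[adj[i, ]]), numeric(1))
      if (identical(g_new, g)) break
      g <- g_new
    }
    expect_equal(cl3$n_clusters, length(unique(g)))
  }
})

test_that("cluster area is the exact union area in mm^2", {
  one <- make_cells(0, 0, "tumor")
  cl <- build_tumor_clusters(one, merge_radius = 15, min_cells = 1)
  expect_equal(cluster_area(cl), pi * 15^2 / 1e6, tolerance = 0.01)

  # coincident cells: union semantics, no double counting
  two_same <- make_cells(c(0, 0), c(0, 0), "tumor")
  cl2 <- build_tumor_clusters(two_same, merge_radius = 15, min_cells = 1)
  expect_equal(cluster_area(cl2), cluster_area(cl))

  # disjoint clusters: additive
  far <- make_cells(c(0, 500), c(0, 0), "tumor")
  cl3 <- build_tumor_clusters(far, merge_radius = 15, min_cells = 1)
  expect_equal(cluster_area(cl3), 2 * cluster_area(cl), tolerance = 1e-6)

  # area bound: n * pi * r^2
  set.seed(4)
  x <- runif(50, 0, 200); y <- runif(50, 0, 200)
  cl4 <- build_tumor_clusters(make_cells(x, y, "tumor"),
                              merge_radius = 15, min_cells = 1)
  expect_lte(cluster_area(cl4), 50 * pi * 15^2 / 1e6)
})

test_that("exclusion regions reduce the area denominator only", {
  one <- make_cells(0, 0, "tumor")
  box <- list(list(x = c(-50, 50, 50, -50), y = c(-50, -50, 50, 50)))
  cl <- build_tumor_clusters(one, merge_radius = 15, min_cells = 1,
                             exclusions = box)
  expect_equal(cluster_area(cl), 0)
  expect_true(cl$exclusions_applied)
  # outline is kept: distances still defined
  expect_lt(signed_distance(cl, 0, 0), 0)

  half <- list(list(x = c(0, 50, 50, 0), y = c(-50, -50, 50, 50)))
  cl2 <- build_tumor_clusters(one, merge_radius = 15, min_cells = 1,
                              exclusions = half)
  expect_equal(cluster_area(cl2),
               pi * 15^2 / 2 / 1e6, tolerance = 0.01)
})

test_that("min_cells filters weakly supported components", {
  cells <- make_cells(c(0, 5, 10, 400), c(0, 0, 0, 0), "tumor")
  cl <- build_tumor_clusters(cells, merge_radius = 15, min_cells = 3)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$cells_per_cluster, 3L)
})

test_that("no tumor cells yields an empty set, bad coordinates an error", {
  none <- make_cells(numeric(), numeric(), character())
  cl <- build_tumor_clusters(none, merge_radius = 15)
  expect_equal(cl$n_clusters, 0L)
  expect_equal(cluster_area(cl), 0)
  expect_error(signed_distance(cl, 0, 0), class = "immunozone_error_no_tumor")

  bad <- make_cells(c(0, NA), c(0, 0), "tumor")
  expect_error(build_tumor_clusters(bad, merge_radius = 15),
               class = "immunozone_error_input")
  expect_error(build_tumor_clusters(make_cells(0, 0, "tumor"),
                                    merge_radius = -1),
               class = "immunozone_error_input")
})

test_that("signed distance is negative inside, exact outside", {
  one <- make_cells(0, 0, "tumor")
  cl <- build_tumor_clusters(one, merge_radius = 20, min_cells = 1)
  expect_equal(signed_distance(cl, 0, 0), -20, tolerance = 0.01)
  expect_equal(signed_distance(cl, 50, 0), 30, tolerance = 0.1)
})

test_that("signed distance agrees with a dense boundary-sampling oracle", {
  set.seed(21)
  for (rep in 1:4) {
    sim <- simulate_core(small_core_config(seed = 100 + rep))
    cl <- sim$clusters
    px <- runif(250, -350, 350); py <- runif(250, -350, 350)
    d <- signed_distance(cl, px, py)
    expect_equal(abs(d), oracle_min_distance(cl, px, py), tolerance = 0.5)
    expect_equal(d < 0, oracle_inside(cl, px, py))
  }
})

test_that("clusters are equivariant under rigid motions", {
  set.seed(33)
  x <- runif(30, 0, 150); y <- runif(30, 0, 150)
  cl <- build_tumor_clusters(make_cells(x, y, "tumor"), merge_radius = 15)
  th <- 0.7; dx <- 120; dy <- -45
  xr <- cos(th) * x - sin(th) * y + dx
  yr <- sin(th) * x + cos(th) * y + dy
  clr <- build_tumor_clusters(make_cells(xr, yr, "tumor"), merge_radius = 15)
  # tolerances reflect the fixed-orientation 64-gon disc discretization,
  # which is not itself rotation-invariant
  expect_equal(cluster_area(clr), cluster_area(cl), tolerance = 1e-4)
  expect_equal(clr$n_clusters, cl$n_clusters)
  # distances to matched probe points are preserved
  px <- c(75, 10); py <- c(75, 140)
  pxr <- cos(th) * px - sin(th) * py + dx
  pyr <- sin(th) * px + cos(th) * py + dy
  expect_equal(signed_distance(clr, pxr, pyr), signed_distance(cl, px, py),
               tolerance = 2e-3)
})

test_that("increasing merge radius never increases the cluster count", {
  set.seed(5)
  x <- runif(40, 0, 400); y <- runif(40, 0, 400)
  cells <- make_cells(x, y, "tumor")
  n_prev <- Inf
  for (r in c(10, 20, 40, 80)) {
    n <- build_tumor_clusters(cells, merge_radius = r, min_cells = 1)$n_clusters
    expect_lte(n, n_prev)
    n_prev <- n
  }
})
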