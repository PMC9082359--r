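test_that("simulation is deterministic under a fixed seed", {
  s1 <- simulate_core(small_core_config(seed = 123))
  s2 <- simulate_core(small_core_config(seed = 123))
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$truth$areas_mm2, s2$truth$areas_mm2)
  s3 <- simulate_core(small_core_config(seed = 124))
  expect_false(identical(s1$cells, s3$cells))

  cfg <- cohort_sim_config(n_cases_per_group = c(HR_d = 2, HR_MMR_intact = 2),
                           cores_per_case = 2, core = micro_core_config(),
                           seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$cells, c2$cells)
  expect_identical(c1$annotations, c2$annotations)
  expect_identical(c1$clinical, c2$clinical)
})

test_that("zero immune intensity emits tumor cells only", {
  zero <- default_immune_intensity()
  zero$intensity <- 0
  sim <- simulate_core(small_core_config(seed = 3, immune_intensity = zero))
  expect_true(all(sim$cells$cell_class == "tumor"))
})

test_that("invalid configurations are rejected", {
  expect_error(core_sim_config(core_diameter = -5),
               class = "immunozone_error_config")
  expect_error(core_sim_config(core_diameter = 300),  # clusters cannot fit
               class = "immunozone_error_config")
  bad <- default_immune_intensity()
  bad$intensity[1] <- -1
  expect_error(core_sim_config(immune_intensity = bad),
               class = "immunozone_error_config")
  expect_error(core_sim_config(pdl1_fraction = c(tumor_cell = 1.5,
                                                 lymphocyte = 0,
                                                 macrophage = 0)),
               class = "immunozone_error_config")
  expect_error(
    cohort_sim_config(n_cases_per_group = c(HRD = 5)),
    class = "immunozone_error_config"
  )
})

test_that("emitted counts per compartment are Poisson around intensity x area", {
  # fixed CD8 intra intensity; pipeline-recounted cells vs generator truth
  zs <- numeric(60)
  for (i in seq_len(60)) {
    sim <- simulate_core(small_core_config(seed = 1000 + i))
    counts <- zone_counts(sim$cells, sim$clusters)
    n_obs <- counts$n[counts$phenotype == "CD8" &
                        counts$zone == "intra_tumoral"]
    lam <- 40.5 * sim$truth$areas_mm2[["intra_tumoral"]]
    zs[i] <- (n_obs - lam) / sqrt(lam)
  }
  expect_gte(mean(abs(zs) <= 3), 0.97)
  expect_lt(abs(mean(zs)), 0.5)
})

test_that("the pipeline recount equals the generated compartment counts", {
  # geometry is shared by construction, so zone recounts are exact
  sim <- simulate_core(small_core_config(seed = 55))
  counts <- zone_counts(sim$cells, sim$clusters)
  truth_n <- sim$cells |>
    dplyr::filter(cell_class != "tumor") |>
    nrow()
  expect_equal(sum(counts$n), truth_n)
})

test_that("cohort generation conserves case counts and recovers labels", {
  cfg <- cohort_sim_config(
    n_cases_per_group = c(HR_d = 6, HR_MMR_intact = 7, MMR_d = 2),
    cores_per_case = 2, core = micro_core_config(), seed = 11
  )
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$clinical), 15L)
  expect_equal(nrow(sim$annotations), 15L)
  expect_equal(dplyr::n_distinct(sim$cells$core_id), 30L)
  expect_equal(as.vector(table(sim$clinical$subgroup)[c("HR_d",
                                                        "HR_MMR_intact",
                                                        "MMR_d")]),
               c(6L, 7L, 2L))
  # every generated annotation classifies into its intended subgroup
  labels <- classify_table(sim$annotations)
  joined <- dplyr::inner_join(labels, sim$clinical, by = "case_id")
  expect_equal(as.character(joined$subgroup.x), joined$subgroup.y)
})

test_that("generated annotations are rule-consistent across many draws", {
  for (lbl in c("HR_d", "MMR_d", "HR_MMR_intact")) {
    set.seed(202)
    anns <- purrr::map_dfr(1:150, function(i) {
      immunozone:::simulate_annotation(paste0(lbl, "_", i), lbl)
    })
    out <- classify_table(anns)
    expect_true(all(out$subgroup == lbl), label = lbl)
  }
})

test_that("survival generation matches the configured medians and censoring", {
  cfg <- cohort_sim_config(
    n_cases_per_group = c(HR_d = 25, HR_MMR_intact = 166),
    cores_per_case = 1, core = micro_core_config(), seed = 29
  )
  hit_intact <- logical(10)
  med_hrd <- numeric(10)
  for (r in seq_len(10)) {
    cfg$seed <- 29 + r
    sim <- simulate_cohort(cfg)
    expect_true(all(sim$clinical$time_months <= 60))
    km <- km_logrank(sim$clinical, group = "subgroup")
    med <- setNames(km$medians$median_os, km$medians$group)
    hit_intact[r] <- abs(med[["HR_MMR_intact"]] - 19.9) / 19.9 < 0.25
    med_hrd[r] <- med[["HR_d"]]
  }
  # n = 166: individual replicates recover the median within 25%;
  # n = 25: the KM median is noisy per replicate but unbiased on average
  expect_gte(mean(hit_intact), 0.8)
  expect_equal(mean(med_hrd), 29.1, tolerance = 0.25)
})
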