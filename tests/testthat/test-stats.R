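test_that("wilcoxon comparison: exact branch, invariances", {
  expect_equal(wilcoxon_compare(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(wilcoxon_compare(1:3, 4:6), 0.1)
  # rank statistic: invariant under common strictly monotone transforms
  set.seed(2)
  a <- rnorm(8); b <- rnorm(9) + 0.5
  expect_equal(wilcoxon_compare(a, b), wilcoxon_compare(exp(a), exp(b)))
  expect_error(wilcoxon_compare(numeric(), 1:3),
               class = "immunozone_error_input")
})

test_that("exact wilcoxon agrees with full permutation enumeration", {
  set.seed(7)
  for (m in 2:5) {
    for (n in 2:5) {
      a <- rnorm(m); b <- rnorm(n) + runif(1, -1, 1)
      expect_equal(wilcoxon_compare(a, b), oracle_wilcoxon(a, b),
                   tolerance = 1e-10,
                   label = sprintf("wilcoxon m=%d n=%d", m, n))
    }
  }
})

test_that("fisher exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(6, 19, 0, 163), 2, byrow = TRUE)),
               oracle_fisher(6, 19, 0, 163), tolerance = 1e-9)
  expect_lt(fisher_exact(matrix(c(6, 19, 0, 163), 2, byrow = TRUE)), 1e-5)
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2, byrow = TRUE)), 1.0)
  # symmetry under simultaneous row and column swaps
  t1 <- matrix(c(3, 9, 7, 2), 2)
  t2 <- t1[2:1, 2:1]
  expect_equal(fisher_exact(t1), fisher_exact(t2))
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 class = "immunozone_warn_degenerate")
  expect_equal(p, 1.0)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)),
               class = "immunozone_error_input")
})

test_that("Kaplan-Meier medians match a hand-computed product limit", {
  # 10 uncensored deaths at 1..10: S drops by 1/10 each time; S(5) = 0.5
  d <- tibble::tibble(time_months = 1:10, event = TRUE,
                      group = rep(c("A", "B"), each = 5))
  one <- km_logrank(dplyr::mutate(d, group = "A"))
  expect_equal(one$medians$median_os, 5)

  # identical distributions: high p
  set.seed(31)
  eq <- tibble::tibble(time_months = rep(rexp(30, 0.1), 2), event = TRUE,
                       group = rep(c("A", "B"), each = 30))
  expect_gt(km_logrank(eq)$p_value, 0.99)

  # everyone censored: flat curve, undefined median, no log-rank
  cens <- tibble::tibble(time_months = rep(12, 8), event = FALSE,
                         group = rep(c("A", "B"), each = 4))
  r <- km_logrank(cens)
  expect_true(all(is.na(r$medians$median_os)))
  expect_true(is.na(r$p_value))
  td <- tidy(r)
  expect_true(all(td$survival == 1))

  expect_error(km_logrank(cens[0, ]), class = "immunozone_error_input")
})

test_that("KM curves are non-increasing with S(0) = 1", {
  set.seed(17)
  d <- tibble::tibble(time_months = rexp(40, 0.05),
                      event = runif(40) < 0.7,
                      group = rep(c("A", "B"), 20))
  td <- tidy(km_logrank(d))
  for (g in c("A", "B")) {
    s <- td$survival[td$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(s[1], 1)
  }
})

test_that("log-rank p-values are roughly uniform under the null", {
  set.seed(19)
  p <- replicate(120, {
    d <- tibble::tibble(time_months = rexp(40, 0.08),
                        event = runif(40) < 0.8,
                        group = rep(c("A", "B"), each = 20))
    km_logrank(d)$p_value
  })
  expect_equal(mean(p), 0.5, tolerance = 0.12)
})

test_that("the cohort report covers densities, scores, PD-L1 and survival", {
  cfg <- cohort_sim_config(
    n_cases_per_group = c(HR_d = 5, HR_MMR_intact = 6),
    cores_per_case = 1, core = micro_core_config(), seed = 77
  )
  sim <- simulate_cohort(cfg)
  prof <- profile_cases(sim$cells)
  labels <- classify_table(sim$annotations)
  rep <- compare_cohort(prof, labels, survival = sim$clinical)

  expect_s3_class(rep, "cohort_comparison")
  expect_equal(nrow(rep$densities), 9L)  # 3 phenotypes x 3 zones
  expect_equal(nrow(rep$scores), 2L)     # ratio + CPS
  expect_equal(nrow(rep$pdl1_positivity), 2L)
  expect_equal(nrow(rep$survival$medians), 2L)

  td <- tidy(rep)
  expect_equal(nrow(td), 9L + 2L + 1L + 1L)
  gl <- glance(rep)
  expect_equal(gl$n_comparisons, 11L)

  # an empty comparison group is flagged, not fatal
  rep2 <- compare_cohort(prof, labels[labels$subgroup == "HR_d", ],
                         groups = c("HR_d", "HR_MMR_intact"))
  expect_true(all(!rep2$densities$evaluable))
  expect_true(all(is.na(rep2$densities$p_value)))
})
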