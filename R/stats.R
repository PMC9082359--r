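# Group comparisons: Wilcoxon rank-sum on densities and scores, Fisher's
# exact test on PD-L1 positivity, Kaplan-Meier / log-rank for overall
# survival, and the assembled cohort report.

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Exact enumeration when the combined sample size is at most
#' `exact_max_n` and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b Numeric samples (both non-empty).
#' @param exact_max_n Largest combined n for the exact branch (default 20).
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_compare(1:3, 4:6)  # 2/20 = 0.1
#' @export
wilcoxon_compare <- function(a, b, exact_max_n = 20) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both groups must be non-empty.", class = "immunozone_error_input")
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- (length(a) + length(b)) <= exact_max_n && !ties
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = TRUE)$p.value
  )
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities, with fixed margins, of every table as
#' or less probable than the observed one.  Degenerate margins (an empty
#' row or column) leave the test undefined; `p = 1` is returned with a
#' warning.
#'
#' @param x A 2x2 matrix of non-negative counts, rows = groups, columns =
#'   outcome yes/no.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(6, 19, 0, 163), 2, byrow = TRUE))
#' @export
fisher_exact <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L)) || any(x < 0) || any(x != round(x))) {
    abort("`x` must be a 2x2 matrix of non-negative integer counts.",
          class = "immunozone_error_input")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    warn("Degenerate margin: Fisher's exact test undefined, returning p = 1.",
         class = "immunozone_warn_degenerate")
    return(1)
  }
  fisher.test(x, alternative = "two.sided")$p.value
}

#' Kaplan-Meier curves and log-rank comparison for two groups
#'
#' @param data Data frame with survival records.
#' @param time,event,group Column names (strings) for follow-up time
#'   (months), event indicator (TRUE/1 = death) and group label.
#' @return A `km_result` with `$medians` (per-group median overall survival,
#'   `NA` while the curve stays above 0.5), `$p_value` (log-rank, 1 df),
#'   and the underlying `survival::survfit` object.  Groups without any
#'   record raise an error; the log-rank p is `NA` unless both groups have
#'   at least one event.
#' @export
km_logrank <- function(data, time = "time_months", event = "event",
                       group = "group") {
  stopifnot(is.data.frame(data))
  d <- tibble(time = as.numeric(data[[time]]),
              event = as.integer(as.logical(data[[event]])),
              group = as.character(data[[group]]))
  if (any(is.na(d$time)) || any(d$time < 0)) {
    abort("Survival times must be non-negative and non-missing.",
          class = "immunozone_error_input")
  }
  groups <- unique(d$group)
  if (length(groups) < 1L || any(table(d$group) == 0L)) {
    abort("Each group needs at least one record.",
          class = "immunozone_error_input")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(groups[1L], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  # median: earliest time at which the product-limit curve drops to <= 0.5
  medians <- tibble(group = sort(unique(d$group))) |>
    mutate(
      n = as.integer(table(d$group)[.data$group]),
      events = as.integer(tapply(d$event, d$group, sum)[.data$group]),
      median_os = unname(vapply(.data$group, function(g) {
        t <- fit$time[strata == g & fit$surv <= 0.5]
        if (length(t) == 0L) NA_real_ else min(t)
      }, numeric(1)))
    )
  p <- NA_real_
  if (length(groups) == 2L && all(tapply(d$event, d$group, sum) >= 1)) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    p <- as.numeric(1 - pchisq(lr$chisq, df = 1))
  }
  structure(list(medians = medians, p_value = p, fit = fit),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("<km_result> log-rank p =", format.pval(x$p_value, digits = 3), "\n")
  print(x$medians)
  invisible(x)
}

#' @export
tidy.km_result <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  strata <- if (is.null(s$strata)) rep("all", length(s$time))
            else sub("^group=", "", as.character(s$strata))
  tibble(group = strata, time = s$time, n_risk = s$n.risk,
         n_event = s$n.event, survival = s$surv,
         std_error = s$std.err, conf_low = s$lower, conf_high = s$upper)
}

#' @export
glance.km_result <- function(x, ...) {
  tibble(n = sum(x$medians$n), events = sum(x$medians$events),
         p_value = x$p_value)
}

#' Compare immune profiles, PD-L1 positivity and survival between subgroups
#'
#' Assembles the full cohort report for two molecular subgroups: per
#' (phenotype, compartment) density means +/- SD with a Wilcoxon rank-sum
#' p-value (computed on the raw, untransformed densities), the
#' CD8+:FOXP3+ ratio and CPS comparisons, Fisher's exact test on the CPS
#' >= 1 positivity proportions, and Kaplan-Meier medians with the log-rank
#' p-value.  P-values are reported unadjusted by default; `p_adjust =
#' "BH"` applies a Benjamini-Hochberg correction across the density and
#' score comparisons.
#'
#' @param profiles An `immune_profiles` object from [profile_cases()].
#' @param labels Tibble `case_id`, `subgroup` (e.g. from
#'   [classify_table()]).
#' @param survival Optional tibble `case_id`, `time_months`, `event`.
#' @param groups The two subgroup labels to compare (first = test group,
#'   second = reference).
#' @param survival_exclude Case ids excluded from the survival analysis
#'   only (e.g. deaths from a competing primary).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A `cohort_comparison` object with tibbles `$densities`,
#'   `$scores`, `$pdl1_positivity`, `$survival`.
#' @export
compare_cohort <- function(profiles, labels, survival = NULL,
                           groups = c("HR_d", "HR_MMR_intact"),
                           survival_exclude = character(),
                           p_adjust = c("none", "BH")) {
  stopifnot(inherits(profiles, "immune_profiles"))
  p_adjust <- match.arg(p_adjust)
  lab <- tibble(case_id = as.character(labels$case_id),
                subgroup = as.character(labels$subgroup)) |>
    filter(.data$subgroup %in% groups)

  two_group <- function(values, case_ids) {
    df <- tibble(case_id = as.character(case_ids), value = values) |>
      inner_join(lab, by = "case_id") |>
      filter(!is.na(.data$value))
    va <- df$value[df$subgroup == groups[1L]]
    vb <- df$value[df$subgroup == groups[2L]]
    tibble(
      n_1 = length(va), n_2 = length(vb),
      mean_1 = if (length(va)) mean(va) else NA_real_,
      sd_1 = if (length(va) > 1) sd(va) else NA_real_,
      mean_2 = if (length(vb)) mean(vb) else NA_real_,
      sd_2 = if (length(vb) > 1) sd(vb) else NA_real_,
      p_value = if (length(va) && length(vb)) wilcoxon_compare(va, vb)
                else NA_real_,
      evaluable = length(va) > 0 && length(vb) > 0
    )
  }

  densities <- profiles$densities |>
    group_by(.data$phenotype, .data$zone) |>
    group_modify(~ two_group(.x$density, .x$case_id)) |>
    ungroup() |>
    mutate(metric = "density", .before = 1L)

  scores <- bind_rows(
    mutate(two_group(profiles$scores$cd8_foxp3_ratio,
                     profiles$scores$case_id),
           metric = "cd8_foxp3_ratio", .before = 1L),
    mutate(two_group(profiles$scores$cps, profiles$scores$case_id),
           metric = "cps", .before = 1L)
  )

  if (p_adjust == "BH") {
    adj <- p.adjust(c(densities$p_value, scores$p_value), method = "BH")
    densities$p_adjusted <- adj[seq_len(nrow(densities))]
    scores$p_adjusted <- adj[nrow(densities) + seq_len(nrow(scores))]
  }

  pos <- profiles$scores |>
    inner_join(lab, by = "case_id") |>
    filter(!is.na(.data$cps))
  tab <- vapply(groups, function(g) {
    c(sum(pos$cps_positive[pos$subgroup == g]),
      sum(!pos$cps_positive[pos$subgroup == g]))
  }, numeric(2))
  tab <- t(tab)  # rows = groups, cols = positive / negative
  pdl1 <- tibble(
    group = groups,
    n_positive = as.integer(tab[, 1L]),
    n_evaluable = as.integer(rowSums(tab)),
    p_value = if (all(rowSums(tab) > 0)) fisher_exact(tab) else NA_real_
  )

  surv <- NULL
  if (!is.null(survival)) {
    sdat <- tibble(case_id = as.character(survival$case_id),
                   time_months = survival$time_months,
                   event = survival$event) |>
      filter(!.data$case_id %in% survival_exclude) |>
      inner_join(lab, by = "case_id")
    surv <- if (all(groups %in% sdat$subgroup)) {
      km_logrank(sdat, time = "time_months", event = "event",
                 group = "subgroup")
    }
  }

  structure(list(densities = densities, scores = scores,
                 pdl1_positivity = pdl1, survival = surv,
                 groups = groups, p_adjust = p_adjust),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat("<cohort_comparison> ", x$groups[1L], " vs ", x$groups[2L], "\n", sep = "")
  cat("Densities (cells/mm^2, mean +/- SD; Wilcoxon p):\n")
  print(x$densities, n = Inf)
  cat("Scores:\n")
  print(x$scores)
  cat("PD-L1 positivity (CPS >= 1; Fisher p = ",
      format.pval(x$pdl1_positivity$p_value[1L], digits = 3), "):\n", sep = "")
  print(x$pdl1_positivity)
  if (!is.null(x$survival)) print(x$survival)
  invisible(x)
}

#' @export
tidy.cohort_comparison <- function(x, ...) {
  dens <- x$densities |>
    mutate(term = paste(.data$phenotype, .data$zone, sep = "_")) |>
    select(-"phenotype", -"zone")
  sc <- mutate(x$scores, term = .data$metric)
  out <- bind_rows(dens, sc) |>
    select("metric", "term", everything())
  extra <- tibble(
    metric = "pdl1_positivity", term = "cps_ge_1",
    n_1 = x$pdl1_positivity$n_evaluable[1L],
    n_2 = x$pdl1_positivity$n_evaluable[2L],
    p_value = x$pdl1_positivity$p_value[1L],
    evaluable = TRUE
  )
  if (!is.null(x$survival)) {
    m <- x$survival$medians
    extra <- bind_rows(extra, tibble(
      metric = "survival", term = "median_os",
      n_1 = m$n[match(x$groups[1L], m$group)],
      n_2 = m$n[match(x$groups[2L], m$group)],
      mean_1 = m$median_os[match(x$groups[1L], m$group)],
      mean_2 = m$median_os[match(x$groups[2L], m$group)],
      p_value = x$survival$p_value, evaluable = TRUE
    ))
  }
  bind_rows(out, extra)
}

#' @export
glance.cohort_comparison <- function(x, ...) {
  tibble(
    group_1 = x$groups[1L], group_2 = x$groups[2L],
    n_comparisons = nrow(x$densities) + nrow(x$scores),
    n_significant = sum(c(x$densities$p_value, x$scores$p_value) < 0.05,
                        na.rm = TRUE),
    pdl1_p = x$pdl1_positivity$p_value[1L],
    logrank_p = if (!is.null(x$survival)) x$survival$p_value else NA_real_
  )
}
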