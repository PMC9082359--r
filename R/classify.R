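# Rule-based molecular subgroup assignment: HR-d, MMR-d or HR/MMR-intact.
#
# HR-d calling rests on germline BRCA1/BRCA2/PALB2 status refined by the
# HRDetect mutational-signature score when whole-genome sequencing is
# available; a documented low-tumor-cellularity exception accepts scores
# above 0.7, and cases without a germline hit qualify through a score above
# 0.9 plus somatic HR-gene inactivation.  MMR-d calling rests on
# immunohistochemical loss of any MMR protein or an MSIsensor score >= 20;
# germline MMR mutations alone do not qualify.  Cases that cannot be
# evaluated default to HR/MMR-intact.

HR_GENES <- c("BRCA1", "BRCA2", "PALB2")
MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")
SUBGROUPS <- c("HR_MMR_intact", "HR_d", "MMR_d")

#' Mismatch-repair deficiency status
#'
#' A case is MMR-deficient if any assessed MMR protein (MLH1, MSH2, MSH6,
#' PMS2) shows immunohistochemical loss, or if its MSIsensor score is at or
#' above the cutoff.  Germline MMR-gene mutations do not by themselves
#' confer MMR-d status.  A case with neither assay available is treated as
#' not deficient (unevaluated).
#'
#' @param mmr_ihc Character vector of per-protein IHC calls among
#'   `"retained"`, `"lost"`, `"not_assessed"` (any length, `NULL` if not
#'   done).
#' @param msisensor MSIsensor score (`NA` or `NULL` if unavailable).
#' @param msisensor_cutoff MSI-high cutoff (default 20).
#' @return `TRUE` if MMR-deficient.
#' @export
mmr_status <- function(mmr_ihc = NULL, msisensor = NULL,
                       msisensor_cutoff = 20) {
  ihc_lost <- !is.null(mmr_ihc) && any(mmr_ihc == "lost", na.rm = TRUE)
  msi_high <- !is.null(msisensor) && !all(is.na(msisensor)) &&
    any(msisensor >= msisensor_cutoff, na.rm = TRUE)
  isTRUE(ihc_lost || msi_high)
}

#' Classify one case into a molecular subgroup
#'
#' Decision order: (1) MMR deficiency by [mmr_status()] takes precedence;
#' (2) a germline HR-gene carrier is HR-d when no HRDetect score is
#' available, when the score is >= `hrdetect_germline`, or — for flagged
#' low-tumor-cellularity cases — when the score exceeds
#' `hrdetect_low_cellularity`; a carrier below threshold is considered
#' HR-intact; (3) without a germline hit, HR-d requires an HRDetect score
#' strictly above `hrdetect_somatic` together with somatic HR-gene
#' inactivation; (4) everything else, including unevaluable cases, is
#' HR/MMR-intact.
#'
#' @param germline_hr_gene `"BRCA1"`, `"BRCA2"`, `"PALB2"`, or `NA`/`""`.
#' @param somatic_hr_inactivation Logical: somatic HR-gene inactivation
#'   (biallelic hit, LOH, deletion) on tumor sequencing.
#' @param hrdetect HRDetect score in `[0, 1]`, or `NA` if unavailable.
#' @param low_cellularity Logical: low-tumor-cellularity flag enabling the
#'   relaxed threshold.
#' @param mmr_ihc,msisensor Passed to [mmr_status()].
#' @param hrdetect_germline Inclusive germline-path threshold (default 0.9).
#' @param hrdetect_somatic Exclusive somatic-path threshold (default 0.9).
#' @param hrdetect_low_cellularity Exclusive low-cellularity threshold
#'   (default 0.7).
#' @param msisensor_cutoff MSI-high cutoff (default 20).
#' @return List with `label` (one of `HR_d`, `MMR_d`, `HR_MMR_intact`) and
#'   `rule_fired` naming the decision path.
#' @export
classify_case <- function(germline_hr_gene = NA, somatic_hr_inactivation = FALSE,
                          hrdetect = NA, low_cellularity = FALSE,
                          mmr_ihc = NULL, msisensor = NULL,
                          hrdetect_germline = 0.9, hrdetect_somatic = 0.9,
                          hrdetect_low_cellularity = 0.7,
                          msisensor_cutoff = 20) {
  if (!is.na(hrdetect) && (hrdetect < 0 || hrdetect > 1)) {
    abort("`hrdetect` must lie in [0, 1].", class = "immunozone_error_input")
  }
  gene <- if (is.null(germline_hr_gene) || is.na(germline_hr_gene) ||
              !nzchar(germline_hr_gene)) NA_character_ else germline_hr_gene
  if (!is.na(gene) && !gene %in% HR_GENES) {
    abort(paste0("Unknown germline HR gene: ", gene),
          class = "immunozone_error_input")
  }

  if (mmr_status(mmr_ihc, msisensor, msisensor_cutoff)) {
    rule <- if (!is.null(mmr_ihc) && any(mmr_ihc == "lost", na.rm = TRUE))
      "mmr_ihc_loss" else "msisensor_high"
    return(list(label = "MMR_d", rule_fired = rule))
  }
  if (!is.na(gene)) {
    if (is.na(hrdetect)) {
      return(list(label = "HR_d", rule_fired = "germline_no_hrdetect"))
    }
    if (hrdetect >= hrdetect_germline) {
      return(list(label = "HR_d", rule_fired = "germline_hrdetect_high"))
    }
    if (isTRUE(low_cellularity) && hrdetect > hrdetect_low_cellularity) {
      return(list(label = "HR_d", rule_fired = "germline_low_cellularity"))
    }
    return(list(label = "HR_MMR_intact",
                rule_fired = "germline_below_threshold"))
  }
  if (!is.na(hrdetect) && hrdetect > hrdetect_somatic &&
      isTRUE(somatic_hr_inactivation)) {
    return(list(label = "HR_d", rule_fired = "somatic_hrdetect_high"))
  }
  list(label = "HR_MMR_intact", rule_fired = "default_intact")
}

#' Classify an annotation table
#'
#' Applies [classify_case()] to every row of a molecular-annotation table.
#'
#' @param annotations Data frame with columns `case_id`,
#'   `germline_hr_gene`, `somatic_hr_inactivation`, `hrdetect`,
#'   `low_cellularity`, the per-protein IHC columns `mmr_ihc_mlh1`,
#'   `mmr_ihc_msh2`, `mmr_ihc_msh6`, `mmr_ihc_pms2`, and `msisensor`.
#'   Missing IHC columns or scores are treated as not assessed.
#' @param ... Threshold overrides passed to [classify_case()].
#' @return A tibble `case_id`, `subgroup` (factor), `rule_fired`; subgroup
#'   counts are attached as the `"counts"` attribute and shown by
#'   `summary()`/`table()` on the `subgroup` column.
#' @examples
#' path <- system.file("extdata", "pdac_hrd_annotations.tsv",
#'                     package = "immunozone")
#' labels <- classify_table(read_annotation_table(path))
#' table(labels$subgroup)
#' @export
classify_table <- function(annotations, ...) {
  stopifnot(is.data.frame(annotations))
  if (anyDuplicated(annotations$case_id)) {
    abort("Duplicate case_id in annotation table.",
          class = "immunozone_error_input")
  }
  ihc_cols <- paste0("mmr_ihc_", tolower(MMR_GENES))
  res <- purrr::map(seq_len(nrow(annotations)), function(i) {
    row <- annotations[i, ]
    ihc <- unlist(row[intersect(ihc_cols, names(row))], use.names = FALSE)
    if (length(ihc) == 0L || all(is.na(ihc) | ihc == "not_assessed")) ihc <- NULL
    classify_case(
      germline_hr_gene = row$germline_hr_gene %||% NA,
      somatic_hr_inactivation = isTRUE(row$somatic_hr_inactivation),
      hrdetect = row$hrdetect %||% NA,
      low_cellularity = isTRUE(row$low_cellularity),
      mmr_ihc = ihc,
      msisensor = row$msisensor %||% NULL,
      ...
    )
  })
  out <- tibble(
    case_id = annotations$case_id,
    subgroup = factor(purrr::map_chr(res, "label"), levels = SUBGROUPS),
    rule_fired = purrr::map_chr(res, "rule_fired")
  )
  attr(out, "counts") <- table(out$subgroup)
  out
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x
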