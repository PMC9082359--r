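test_that("MMR status requires assay evidence, not germline status alone", {
  expect_true(mmr_status(mmr_ihc = c("retained", "lost", "lost", "retained")))
  expect_false(mmr_status(mmr_ihc = rep("retained", 4), msisensor = 1.76))
  expect_true(mmr_status(msisensor = 25))
  expect_false(mmr_status(msisensor = 19.9))
  expect_false(mmr_status())  # nothing assessed -> treated as not deficient
  # germline MMR mutation with retained proteins stays intact
  lbl <- classify_case(mmr_ihc = rep("retained", 4))
  expect_equal(lbl$label, "HR_MMR_intact")
})

test_that("HR-d decision paths fire in the documented order", {
  # somatic-only path: no germline hit, high score + somatic inactivation
  s <- classify_case(somatic_hr_inactivation = TRUE, hrdetect = 0.999)
  expect_equal(s$label, "HR_d")
  expect_equal(s$rule_fired, "somatic_hrdetect_high")

  # low-cellularity exception: 0.742 with the override flag
  lc <- classify_case(germline_hr_gene = "PALB2", hrdetect = 0.742,
                      low_cellularity = TRUE)
  expect_equal(lc$label, "HR_d")
  expect_equal(lc$rule_fired, "germline_low_cellularity")

  # germline carrier failing the threshold is considered HR-intact
  expect_equal(classify_case("BRCA2", hrdetect = 0.30)$label, "HR_MMR_intact")

  # MMR deficiency takes precedence over a germline HR path
  m <- classify_case(germline_hr_gene = "BRCA2",
                     mmr_ihc = c("retained", "lost", "lost", "retained"))
  expect_equal(m$label, "MMR_d")

  # germline carrier without a score stays HR-d
  expect_equal(classify_case("BRCA1")$label, "HR_d")
})

test_that("threshold boundaries are inclusive/exclusive exactly as documented", {
  expect_equal(classify_case("BRCA2", hrdetect = 0.9)$label, "HR_d")
  expect_equal(classify_case(somatic_hr_inactivation = TRUE,
                             hrdetect = 0.9)$label, "HR_MMR_intact")
  expect_equal(classify_case("PALB2", hrdetect = 0.7,
                             low_cellularity = TRUE)$label, "HR_MMR_intact")
  expect_true(mmr_status(msisensor = 20))
})

test_that("raising HRDetect never moves a germline carrier out of HR-d", {
  scores <- seq(0, 1, by = 0.05)
  labels <- vapply(scores,
                   function(s) classify_case("BRCA2", hrdetect = s)$label,
                   character(1))
  in_hrd <- labels == "HR_d"
  expect_true(all(diff(in_hrd) >= 0))
})

test_that("the bundled annotation table classifies into 25 HR-d and 1 MMR-d", {
  path <- system.file("extdata", "pdac_hrd_annotations.tsv",
                      package = "immunozone")
  labels <- classify_table(read_annotation_table(path))
  counts <- table(labels$subgroup)
  expect_equal(unname(counts[["HR_d"]]), 25L)
  expect_equal(unname(counts[["MMR_d"]]), 1L)
  expect_equal(sum(counts), nrow(labels))

  lbl <- function(id) as.character(labels$subgroup[labels$case_id == id])
  rule <- function(id) labels$rule_fired[labels$case_id == id]
  expect_equal(lbl("PCSI_0075"), "HR_d")
  expect_equal(rule("PCSI_0075"), "somatic_hrdetect_high")
  expect_equal(lbl("PCSI_0472"), "HR_d")
  expect_equal(lbl("303.001"), "HR_d")
  expect_equal(rule("303.001"), "germline_low_cellularity")
  expect_equal(lbl("750.001"), "MMR_d")
  expect_equal(rule("750.001"), "mmr_ihc_loss")
})

test_that("classify_table validates ids and handles empty input", {
  dup <- tibble::tibble(case_id = c("a", "a"), germline_hr_gene = NA,
                        somatic_hr_inactivation = FALSE, hrdetect = NA,
                        low_cellularity = FALSE, msisensor = NA)
  expect_error(classify_table(dup), class = "immunozone_error_input")

  empty <- dup[0, ]
  out <- classify_table(empty)
  expect_equal(nrow(out), 0L)
  expect_equal(sum(attr(out, "counts")), 0L)
})
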