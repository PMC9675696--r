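test_that("the reconstructed reference cohort has the published composition", {
  cohort <- build_reference_cohort()
  expect_equal(nrow(cohort), 113)
  expect_false(anyDuplicated(cohort$id) > 0)
  counts <- table(cohort$reference_type)
  expect_equal(unname(counts[["gonadotroph"]]), 45)
  expect_equal(unname(counts[["corticotroph"]]), 14)
  expect_equal(unname(counts[["lactotroph"]]), 21)
  expect_equal(unname(counts[["plurihormonal_no_distinct_lineage"]]), 11)
  expect_equal(unname(counts[["null_cell"]]), 1)
  # all 113 profiles are fully performed (the cohort doubles as oracles)
  for (m in all_markers()) expect_false(any(cohort[[m]] == "not_performed"))
})

test_that("full-panel classification reproduces the published type table", {
  cohort <- build_reference_cohort()
  cc <- classify_cohort(cohort)
  freq <- cc$frequency
  get <- function(col, type) freq[[col]][freq$type == type]
  expected <- list(
    somatotroph = c(11, 9.7, 10), lactotroph = c(21, 18.6, 20),
    mammosomatotroph = c(3, 2.7, 3), thyrotroph = c(2, 1.8, 1),
    mature_plurihormonal_PIT1 = c(1, 0.9, 1), immature_PIT1 = c(2, 1.8, 1),
    acidophil_stem_cell = c(0, 0, 0),
    mixed_somatotroph_lactotroph = c(2, 1.8, 1),
    corticotroph = c(14, 12.4, 10), gonadotroph = c(45, 39.8, 0),
    plurihormonal_no_distinct_lineage = c(11, 9.7, 6), null_cell = c(1, 0.9, 0)
  )
  for (type in names(expected)) {
    expect_equal(get("n", type), expected[[type]][1], label = type)
    expect_equal(get("pct", type), expected[[type]][2], label = type)
    expect_equal(get("n_functioning", type), expected[[type]][3], label = type)
  }
  # the classifier recovers every record's reference type
  expect_equal(cc$results$type, cohort$reference_type)
  # 101 tumours arise from a distinct cell lineage
  expect_equal(sum(cc$results$lineage %in% c("SF1", "TPIT", "PIT1")), 101)
})

test_that("specific published no-distinct-lineage rows appear verbatim", {
  cohort <- build_reference_cohort()
  # the acromegalic case positive for all three TFs plus GH and FSH
  hit <- cohort$clinical == "acromegaly" &
    cohort$PIT1 == "positive" & cohort$SF1 == "positive" &
    cohort$TPIT == "positive" & cohort$GH == "positive" &
    cohort$FSH == "positive" & cohort$PRL == "negative" &
    cohort$TSH == "negative" & cohort$ACTH == "negative" &
    cohort$LH == "negative"
  expect_equal(sum(hit), 1)
  # the TF-negative tumour expressing all three PIT1-lineage hormones
  hit2 <- cohort$PIT1 == "negative" & cohort$SF1 == "negative" &
    cohort$TPIT == "negative" & cohort$PRL == "positive" &
    cohort$TSH == "positive" & cohort$GH == "positive"
  expect_equal(sum(hit2), 1)
})

test_that("cohort CSV write/read round-trips losslessly", {
  cohort <- build_reference_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  rownames(cohort) <- rownames(back) <- NULL
  expect_equal(back, cohort)

  # partial profiles and unknown flags survive the trip
  partial <- tumour_record("p1", ihc_profile(positive = "SF1",
                                             negative = c("TPIT", "PIT1")))
  write_cohort(partial, path)
  back <- read_cohort(path)
  expect_equal(back$LH, "not_performed")
  expect_true(is.na(back$monomorphous))
})

test_that("cohort readers validate input and report the location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,SF1,TPIT,PIT1,banana", "a,+,-,-,1"), path)
  expect_error(read_cohort(path), "banana")

  writeLines(c("id,SF1,TPIT,PIT1", "a,+,-,-", "b,weak,-,-"), path)
  expect_error(read_cohort(path), "row 2, column SF1")

  writeLines(c("id,SF1,TPIT,PIT1", "a,+,-,-", "a,+,-,-"), path)
  expect_error(read_cohort(path), "duplicate")

  writeLines(c("id,SF1,TPIT,PIT1,reference_type", "a,+,-,-,adenoma"), path)
  expect_error(read_cohort(path), "adenoma")

  # percentages in cells are binarized on read; missing columns allowed
  writeLines(c("id,SF1,TPIT,PIT1", "a,45,-,2"), path)
  cohort <- read_cohort(path)
  expect_equal(cohort$SF1, "positive")
  expect_equal(cohort$PIT1, "negative")
  expect_equal(cohort$GH, "not_performed")
})

test_that("the packaged reference cohort CSV matches the in-code builder", {
  path <- system.file("extdata", "reference_cohort.csv", package = "pittriage")
  packaged <- read_cohort(path)
  built <- build_reference_cohort()
  rownames(packaged) <- rownames(built) <- NULL
  expect_equal(packaged, built)
})
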