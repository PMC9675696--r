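full_profile <- function(pos) {
  ihc_profile(positive = pos, negative = setdiff(all_markers(), pos))
}

test_that("no-distinct-lineage branches: null cell and plurihormonal", {
  # all nine stains negative -> null cell
  expect_equal(classify(full_profile(character()))$type, "null_cell")
  # zero TFs but hormone-positive -> plurihormonal
  expect_equal(classify(full_profile(c("PRL", "TSH", "GH")))$type,
               "plurihormonal_no_distinct_lineage")
  # multiple TFs -> plurihormonal regardless of hormones
  expect_equal(classify(full_profile(c("PIT1", "SF1", "PRL")))$type,
               "plurihormonal_no_distinct_lineage")
  expect_equal(classify(full_profile(c("SF1", "TPIT")))$type,
               "plurihormonal_no_distinct_lineage")
})

test_that("null cell is a diagnosis of exclusion", {
  # zero TFs with an unperformed hormone can never be null cell
  p <- ihc_profile(negative = setdiff(all_markers(), "FSH"),
                   not_performed = "FSH")
  cl <- classify(p)
  expect_equal(cl$type, "unclassifiable")
  expect_match(cl$warnings, "FSH", all = FALSE)
})

test_that("single SF1 or TPIT settles the type without hormones", {
  gon <- classify(full_profile(c("SF1", "FSH", "LH")))
  expect_equal(gon$type, "gonadotroph")
  expect_equal(gon$lineage, "SF1")
  expect_length(gon$warnings, 0)

  # hormone results never alter a single-TF type; they only warn
  odd <- classify(full_profile(c("SF1", "GH")))
  expect_equal(odd$type, "gonadotroph")
  expect_match(odd$warnings, "out-of-lineage.*GH", all = FALSE)

  cor <- classify(full_profile(c("TPIT", "ACTH")))
  expect_equal(cor$type, "corticotroph")
  expect_length(cor$warnings, 0)

  # TPIT+/ACTH-: hormonally silent (whispering) corticotroph
  silent <- classify(full_profile("TPIT"))
  expect_equal(silent$type, "corticotroph")
  expect_match(silent$warnings, "silent", all = FALSE)

  # SF1/TPIT types resolve even with hormones unperformed (tiered plans)
  expect_equal(classify(ihc_profile(positive = "SF1",
                                    negative = c("TPIT", "PIT1")))$type,
               "gonadotroph")
})

test_that("PIT1 hormone sub-table resolves the eight PIT1-lineage types", {
  expect_equal(classify(full_profile(c("PIT1", "GH")))$type, "somatotroph")
  expect_equal(classify(full_profile(c("PIT1", "PRL")))$type, "lactotroph")
  expect_equal(classify(full_profile(c("PIT1", "TSH")))$type, "thyrotroph")
  expect_equal(classify(full_profile(c("PIT1", "GH", "PRL", "TSH")))$type,
               "mature_plurihormonal_PIT1")
  expect_equal(classify(full_profile(c("PIT1", "GH", "TSH")))$type,
               "mature_plurihormonal_PIT1")

  gp <- full_profile(c("PIT1", "GH", "PRL"))
  expect_equal(classify(gp, morphology_flags(monomorphous = TRUE))$type,
               "mammosomatotroph")
  expect_equal(classify(gp, morphology_flags(monomorphous = FALSE))$type,
               "mixed_somatotroph_lactotroph")
  flag_absent <- classify(gp)
  expect_equal(flag_absent$type, "mammosomatotroph")
  expect_match(flag_absent$warnings, "monomorphous", all = FALSE)

  expect_equal(classify(gp, morphology_flags(immature = TRUE))$type,
               "immature_PIT1")
  # acidophil stem cell features take precedence over the PRL+ rows
  expect_equal(classify(full_profile(c("PIT1", "PRL")),
                        morphology_flags(acidophil_stem_cell_features = TRUE))$type,
               "acidophil_stem_cell")

  hs <- classify(full_profile("PIT1"))
  expect_equal(hs$type, "immature_PIT1")
  expect_match(hs$warnings, "hormone-silent", all = FALSE)
})

test_that("missing required stains give errors or unclassifiable, as tiered", {
  expect_error(classify(ihc_profile(positive = "SF1", negative = "TPIT",
                                    not_performed = "PIT1")),
               "PIT1")
  pit1_no_hormones <- ihc_profile(positive = "PIT1",
                                  negative = c("SF1", "TPIT"))
  cl <- classify(pit1_no_hormones)
  expect_equal(cl$type, "unclassifiable")
  expect_match(cl$warnings, "PRL, TSH, GH", all = FALSE)
})

test_that("classify is exhaustive, deterministic and lineage-consistent", {
  profiles <- enumerate_profiles()
  expect_length(profiles, 512)
  for (p in profiles) {
    cl <- classify(p)
    expect_false(cl$type == "unclassifiable")
    expect_true(length(cl$rationale) >= 2)
    n_tf <- sum(p[tf_markers()] == "positive")
    expect_identical(cl$lineage %in% c("SF1", "TPIT", "PIT1"), n_tf == 1)
    # purity: identical input, identical output
    expect_identical(classify(p), cl)
  }
})

test_that("the 12 published no-distinct-lineage profiles reproduce exactly", {
  ndl <- no_distinct_lineage_profiles()
  expect_equal(nrow(ndl), 12)
  cc <- classify_cohort(ndl)
  expect_equal(sum(cc$results$type == "plurihormonal_no_distinct_lineage"), 11)
  expect_equal(sum(cc$results$type == "null_cell"), 1)
  # printed type column matches the classifier's verdict case by case
  expect_equal(cc$results$type, ndl$reference_type)
  # the null cell case is the clinically non-functioning all-negative one
  expect_equal(ndl$clinical[cc$results$type == "null_cell"], "non_functioning")
})

test_that("classify_cohort tabulates frequencies with half-up percentages", {
  cohort <- rbind(
    tumour_record("a", ihc_profile(positive = c("SF1", "LH", "FSH"),
                                   negative = setdiff(all_markers(), c("SF1", "LH", "FSH")))),
    tumour_record("b", ihc_profile(positive = c("TPIT", "ACTH"),
                                   negative = setdiff(all_markers(), c("TPIT", "ACTH"))),
                  clinical = "cushing"),
    tumour_record("c", ihc_profile(negative = all_markers()))
  )
  cc <- classify_cohort(cohort)
  freq <- cc$frequency
  expect_equal(freq$n[freq$type == "gonadotroph"], 1)
  # 1/3 = 33.333 -> 33.3; functioning column counts non-"non_functioning"
  expect_equal(freq$pct[freq$type == "corticotroph"], 33.3)
  expect_equal(freq$n_functioning[freq$type == "corticotroph"], 1)
  expect_equal(freq$n_functioning[freq$type == "gonadotroph"], 0)

  empty <- classify_cohort(cohort[0, ])
  expect_equal(nrow(empty$frequency), 0)
  expect_equal(nrow(empty$results), 0)

  # per-record failures are tagged with the record id
  broken <- cohort
  broken$PIT1[1] <- "not_performed"
  expect_error(classify_cohort(broken), "record a")
})

test_that("the PIT1 sub-table is data: an edited rules file changes the call", {
  rules <- who2022_pit1_rules()
  expect_true(all(c("rule_id", "type", "warning") %in% names(rules)))
  # flip the flag-unknown GH+PRL+ row to the dimorphous type
  edited <- rules
  edited$type[edited$rule_id == "PIT1_GH_PRL_FLAG_UNKNOWN"] <-
    "mixed_somatotroph_lactotroph"
  gp <- full_profile(c("PIT1", "GH", "PRL"))
  expect_equal(classify(gp, rules = edited)$type,
               "mixed_somatotroph_lactotroph")
})
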