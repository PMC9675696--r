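#' WHO 2022 tumour types
#'
#' The twelve WHO 2022 types of pituitary neuroendocrine tumour plus the
#' `unclassifiable` sentinel returned when a required stain was not
#' performed. Each type belongs to one transcription-factor-defined lineage
#' (SF1, TPIT, PIT1) or to none (the no-distinct-lineage group and the
#' sentinel).
#'
#' @return Data frame with columns `type` and `lineage`.
#' @examples
#' tumour_types()
#' @export
tumour_types <- function() {
  data.frame(
    type = c("somatotroph", "lactotroph", "mammosomatotroph", "thyrotroph",
             "mature_plurihormonal_PIT1", "immature_PIT1",
             "acidophil_stem_cell", "mixed_somatotroph_lactotroph",
             "corticotroph", "gonadotroph",
             "plurihormonal_no_distinct_lineage", "null_cell",
             "unclassifiable"),
    lineage = c(rep("PIT1", 8), "TPIT", "SF1", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' @rdname tumour_types
#' @export
tumour_type_names <- function() tumour_types()$type

type_lineage <- function(type) {
  tt <- tumour_types()
  tt$lineage[match(type, tt$type)]
}

# Cache for the packaged PIT1 sub-table.
.pittriage_env <- new.env(parent = emptyenv())

#' PIT1-lineage hormone decision sub-table
#'
#' The rules applied to a tumour whose only positive transcription factor is
#' PIT1, matched top-to-bottom against the (GH, PRL, TSH) pattern and the
#' morphology flags; the first matching row fires. Shipped as an editable
#' CSV (`system.file("extdata", "who2022_pit1_rules.csv", package =
#' "pittriage")`) so the convention distinguishing, e.g., mammosomatotroph
#' from mixed somatotroph-lactotroph tumours can be audited or replaced.
#' Pattern cells take "+", "-", or "*" (any); flag cells take "true",
#' "false", "na" (flag unknown) or "*".
#'
#' @param path Optional path to an alternative rules CSV.
#' @return Data frame with columns `rule_id`, `GH`, `PRL`, `TSH`,
#'   `monomorphous`, `immature`, `acidophil_stem_cell_features`, `type`,
#'   `warning`.
#' @export
who2022_pit1_rules <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pittriage_env$pit1_rules)) return(.pittriage_env$pit1_rules)
    path <- system.file("extdata", "who2022_pit1_rules.csv",
                        package = "pittriage")
    rules <- utils::read.csv(path, colClasses = "character")
    .pittriage_env$pit1_rules <- rules
    return(rules)
  }
  utils::read.csv(path, colClasses = "character")
}

match_flag_cell <- function(cell, flag) {
  switch(cell,
         "*" = TRUE,
         "true" = isTRUE(flag),
         "false" = identical(flag, FALSE),
         "na" = is.na(flag),
         stop("bad flag cell in rules file: ", cell, call. = FALSE))
}

match_pattern_cell <- function(cell, status) {
  cell == "*" ||
    (cell == "+" && status == "positive") ||
    (cell == "-" && status == "negative")
}

# Resolve the PIT1 sub-table for a profile whose single positive TF is PIT1.
# GH/PRL/TSH are guaranteed performed by the caller.
apply_pit1_rules <- function(profile, morphology, rules) {
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    ok <- match_pattern_cell(r$GH, profile[["GH"]]) &&
      match_pattern_cell(r$PRL, profile[["PRL"]]) &&
      match_pattern_cell(r$TSH, profile[["TSH"]]) &&
      match_flag_cell(r$monomorphous, morphology[["monomorphous"]]) &&
      match_flag_cell(r$immature, morphology[["immature"]]) &&
      match_flag_cell(r$acidophil_stem_cell_features,
                      morphology[["acidophil_stem_cell_features"]])
    if (ok) {
      return(list(type = r$type, rule_id = r$rule_id,
                  warning = if (nzchar(r$warning)) r$warning else character()))
    }
  }
  stop("PIT1 sub-table is not exhaustive; no rule matched", call. = FALSE)
}

new_classification <- function(type, tf_pattern, rationale, warnings) {
  structure(
    list(type = type, lineage = type_lineage(type), tf_pattern = tf_pattern,
         rationale = rationale, warnings = warnings),
    class = "who2022_classification"
  )
}

#' Classify a tumour under the WHO 2022 decision table
#'
#' Deterministic typing of a pituitary tumour from its IHC profile and
#' optional morphology flags. The decision table is evaluated in order:
#' tumours with no positive transcription factor are null cell (all six
#' hormones performed and negative) or plurihormonal with no distinct
#' lineage (any hormone positive); tumours with two or more positive
#' transcription factors are plurihormonal with no distinct lineage; a
#' single positive SF1 or TPIT gives gonadotroph or corticotroph regardless
#' of hormone results (out-of-lineage hormone positivity is reported as a
#' warning, never a type change); a single positive PIT1 is resolved by the
#' (GH, PRL, TSH) sub-table in [who2022_pit1_rules()]. `unclassifiable` is
#' returned only when a stain required by the fired branch was not
#' performed.
#'
#' Clinical presentation is deliberately not an input: the decision table
#' branches on immunohistochemistry alone.
#'
#' @param profile An [ihc_profile()]. All three transcription factor slots
#'   must be performed.
#' @param morphology A [morphology_flags()] vector.
#' @param rules PIT1 sub-table, defaulting to the packaged
#'   [who2022_pit1_rules()].
#' @return Object of class `who2022_classification`: a list with elements
#'   `type`, `lineage`, `tf_pattern` (positive transcription factors),
#'   `rationale` (ordered fired rule ids) and `warnings`.
#' @examples
#' # All nine stains negative: null cell tumour
#' classify(ihc_profile(negative = all_markers()))
#'
#' # SF1-only with gonadotroph hormones
#' classify(ihc_profile(positive = c("SF1", "FSH", "LH"),
#'                      negative = setdiff(all_markers(), c("SF1", "FSH", "LH"))))
#' @export
classify <- function(profile, morphology = morphology_flags(),
                     rules = who2022_pit1_rules()) {
  validate_profile(profile)
  tf <- profile[tf_markers()]
  missing_tf <- names(tf)[tf == "not_performed"]
  if (length(missing_tf) > 0) {
    stop("transcription factor stain(s) not performed: ",
         paste(missing_tf, collapse = ", "), call. = FALSE)
  }
  tf_pos <- names(tf)[tf == "positive"]
  n_tf <- length(tf_pos)
  horm <- profile[hormone_markers()]
  horm_pos <- names(horm)[horm == "positive"]
  horm_missing <- names(horm)[horm == "not_performed"]
  rationale <- sprintf("TF_COUNT=%d", n_tf)
  warnings <- character()

  if (n_tf == 0) {
    if (length(horm_pos) > 0) {
      return(new_classification("plurihormonal_no_distinct_lineage", tf_pos,
                                c(rationale, "TF0_HORMONE_POS_PLURIHORMONAL"),
                                warnings))
    }
    if (length(horm_missing) == 0) {
      return(new_classification("null_cell", tf_pos,
                                c(rationale, "TF0_ALL_NEGATIVE_NULL_CELL"),
                                warnings))
    }
    # Null cell is a diagnosis of exclusion: with hormones unperformed and
    # none positive the case stays unclassifiable.
    warnings <- c(warnings, paste0("hormone stain(s) not performed: ",
                                   paste(horm_missing, collapse = ", ")))
    return(new_classification("unclassifiable", tf_pos,
                              c(rationale, "TF0_INCOMPLETE_UNCLASSIFIABLE"),
                              warnings))
  }

  if (n_tf >= 2) {
    return(new_classification("plurihormonal_no_distinct_lineage", tf_pos,
                              c(rationale, "TF_MULTI_PLURIHORMONAL"),
                              warnings))
  }

  # Exactly one positive transcription factor.
  the_tf <- tf_pos
  out_of_lineage <- setdiff(horm_pos, lineage_hormones(the_tf))
  if (length(out_of_lineage) > 0) {
    warnings <- c(warnings,
                  sprintf("out-of-lineage hormone(s) positive in %s-only tumour: %s",
                          the_tf, paste(out_of_lineage, collapse = ", ")))
  }

  if (the_tf == "SF1") {
    return(new_classification("gonadotroph", tf_pos,
                              c(rationale, "TF1_SF1_GONADOTROPH"), warnings))
  }
  if (the_tf == "TPIT") {
    if (profile[["ACTH"]] == "negative") {
      warnings <- c(warnings,
                    "TPIT+/ACTH-: hormonally silent (whispering) corticotroph")
    }
    return(new_classification("corticotroph", tf_pos,
                              c(rationale, "TF1_TPIT_CORTICOTROPH"), warnings))
  }

  # PIT1 lineage: GH, PRL and TSH must be performed to resolve the type.
  pit1_missing <- intersect(horm_missing, lineage_hormones("PIT1"))
  if (length(pit1_missing) > 0) {
    warnings <- c(warnings,
                  paste0("required PIT1-lineage hormone stain(s) not performed: ",
                         paste(pit1_missing, collapse = ", ")))
    return(new_classification("unclassifiable", tf_pos,
                              c(rationale, "TF1_PIT1_INCOMPLETE"), warnings))
  }
  hit <- apply_pit1_rules(profile, morphology, rules)
  new_classification(hit$type, tf_pos,
                     c(rationale, "TF1_PIT1_SUBTABLE", hit$rule_id),
                     c(warnings, hit$warning))
}

#' @export
print.who2022_classification <- function(x, ...) {
  cat("WHO 2022 type: ", x$type, " (lineage: ", x$lineage, ")\n", sep = "")
  cat("  positive TFs: ",
      if (length(x$tf_pattern)) paste(x$tf_pattern, collapse = ", ") else "none",
      "\n", sep = "")
  cat("  rules fired:  ", paste(x$rationale, collapse = " -> "), "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Classify every tumour in a cohort
#'
#' Applies [classify()] to each row of a cohort data frame and tabulates
#' type frequencies. Percentages are count/N x 100, rounded half-up to one
#' decimal; the functioning column counts records per type whose clinical
#' label is not `non_functioning`.
#'
#' @param cohort Cohort data frame (see [read_cohort()] for the layout).
#' @param rules PIT1 sub-table, defaulting to the packaged rules.
#' @return Object of class `cohort_classification`: list with `results` (one
#'   row per tumour: id, type, lineage, n_tf_positive, warnings) and
#'   `frequency` (type, n, pct, n_functioning).
#' @examples
#' cc <- classify_cohort(build_reference_cohort())
#' cc$frequency
#' @export
classify_cohort <- function(cohort, rules = who2022_pit1_rules()) {
  validate_cohort(cohort)
  n <- nrow(cohort)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    res[[i]] <- tryCatch(
      classify(row_profile(cohort, i), row_morphology(cohort, i), rules),
      error = function(e) {
        stop(sprintf("record %s: %s", cohort$id[i], conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  results <- data.frame(
    id = cohort$id,
    type = vapply(res, `[[`, character(1), "type"),
    lineage = vapply(res, `[[`, character(1), "lineage"),
    n_tf_positive = vapply(res, function(x) length(x$tf_pattern), integer(1)),
    warnings = vapply(res, function(x) paste(x$warnings, collapse = "; "),
                      character(1)),
    stringsAsFactors = FALSE
  )
  if (n == 0) {
    freq <- data.frame(type = character(), n = integer(), pct = numeric(),
                       n_functioning = integer(), stringsAsFactors = FALSE)
  } else {
    types <- tumour_type_names()
    if (!"unclassifiable" %in% results$type) {
      types <- setdiff(types, "unclassifiable")
    }
    cnt <- vapply(types, function(t) sum(results$type == t), integer(1))
    fun <- vapply(types, function(t) {
      sum(results$type == t & cohort$clinical != "non_functioning")
    }, integer(1))
    freq <- data.frame(type = types, n = unname(cnt),
                       pct = round_half_up(unname(cnt) / n * 100, 1),
                       n_functioning = unname(fun), stringsAsFactors = FALSE)
  }
  structure(list(results = results, frequency = freq, n = n,
                 classifications = res),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat("Cohort classification (n = ", x$n, ")\n\n", sep = "")
  print(x$frequency, row.names = FALSE)
  nw <- sum(nzchar(x$results$warnings))
  if (nw > 0) cat("\n", nw, " record(s) carry warnings\n", sep = "")
  invisible(x)
}
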