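#' Stain oracle
#'
#' A stain oracle stands in for the physical tumour block: it holds the true
#' positive/negative result of every one of the nine markers, and a staining
#' strategy reveals only the results it actually orders. All nine slots must
#' be performed.
#'
#' @param profile An [ihc_profile()] with no `not_performed` slot.
#' @return The validated profile, classed `stain_oracle`.
#' @examples
#' stain_oracle(ihc_profile(positive = "SF1",
#'                          negative = setdiff(all_markers(), "SF1")))
#' @export
stain_oracle <- function(profile) {
  validate_profile(profile)
  np <- names(profile)[profile == "not_performed"]
  if (length(np) > 0) {
    stop("a stain oracle must be total; missing true result(s) for: ",
         paste(np, collapse = ", "), call. = FALSE)
  }
  structure(unclass(profile)[all_markers()], class = "stain_oracle")
}

new_stain_plan <- function(strategy, stains, oracle, unit_cost) {
  observed <- ihc_profile(
    positive = stains[oracle[stains] == "positive"],
    negative = stains[oracle[stains] == "negative"]
  )
  structure(
    list(strategy = strategy, stains = stains, observed = observed,
         n_stains = length(stains), unit_cost = unit_cost,
         cost = length(stains) * unit_cost),
    class = "stain_plan"
  )
}

#' Full-panel gold standard staining
#'
#' Orders all nine immunostains (three transcription factors, six hormones)
#' in canonical order — the current routine-practice reference: 9 stains at
#' `unit_cost` each, $450 per tumour at the default $50 AUD per immunostain.
#'
#' @param oracle A [stain_oracle()].
#' @param unit_cost Cost per immunostain; default 50 (AUD).
#' @return Object of class `stain_plan`: strategy name, ordered stains,
#'   observed profile, stain count and cost.
#' @export
run_gold_standard <- function(oracle, unit_cost = 50) {
  oracle <- stain_oracle(oracle)
  new_stain_plan("gold_standard", all_markers(), oracle, unit_cost)
}

#' Tiered transcription-factor-first staining
#'
#' Executes one of the three tiered (reflex) strategies. Tier 1 always
#' orders the full transcription factor panel (SF1, TPIT, PIT1). With zero
#' or two-plus positive transcription factors, every strategy reflexes to
#' the complete six-hormone panel (9 stains total). With exactly one
#' positive transcription factor the strategies differ:
#' \describe{
#'   \item{Algorithm 1}{lineage-confirmatory hormones: SF1 adds LH and FSH
#'     (5 stains); TPIT adds ACTH (4); PIT1 adds all six hormones (9).}
#'   \item{Algorithm 2}{SF1 or TPIT add nothing (3 stains); PIT1 adds all
#'     six hormones (9).}
#'   \item{Algorithm 3}{SF1 or TPIT add nothing (3 stains); PIT1 adds only
#'     its own lineage's hormones GH, PRL, TSH (6).}
#' }
#' The two tiers are batched rounds: all tier-1 results are available
#' before tier 2 is chosen, and there is no stain-by-stain adaptivity
#' within a tier.
#'
#' @param oracle A [stain_oracle()].
#' @param algorithm 1, 2 or 3.
#' @param unit_cost Cost per immunostain; default 50 (AUD).
#' @return A `stain_plan` (see [run_gold_standard()]).
#' @examples
#' sf1_only <- stain_oracle(ihc_profile(positive = c("SF1", "FSH", "LH"),
#'   negative = setdiff(all_markers(), c("SF1", "FSH", "LH"))))
#' run_tiered(sf1_only, algorithm = 3)$n_stains  # 3
#' @export
run_tiered <- function(oracle, algorithm, unit_cost = 50) {
  oracle <- stain_oracle(oracle)
  if (length(algorithm) != 1 || !algorithm %in% c(1, 2, 3)) {
    stop("`algorithm` must be 1, 2 or 3", call. = FALSE)
  }
  tf_pos <- tf_markers()[oracle[tf_markers()] == "positive"]
  tier2 <- if (length(tf_pos) != 1) {
    hormone_markers()
  } else if (algorithm == 1) {
    switch(tf_pos,
           SF1 = c("LH", "FSH"),
           TPIT = "ACTH",
           PIT1 = hormone_markers())
  } else if (algorithm == 2) {
    if (tf_pos == "PIT1") hormone_markers() else character()
  } else {
    if (tf_pos == "PIT1") lineage_hormones("PIT1") else character()
  }
  # Canonical order within tier 2 so plans are byte-for-byte reproducible.
  tier2 <- hormone_markers()[hormone_markers() %in% tier2]
  new_stain_plan(paste0("algorithm_", algorithm),
                 c(tf_markers(), tier2), oracle, unit_cost)
}

#' @export
print.stain_plan <- function(x, ...) {
  cat("Stain plan [", x$strategy, "]: ", x$n_stains, " stains, cost ",
      x$cost, " (", x$unit_cost, "/stain)\n", sep = "")
  cat("  ordered: ", paste(x$stains, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Stain and diagnose with a strategy
#'
#' Runs a staining strategy against the oracle and classifies the tumour
#' from the tier-limited observed profile only: stains the strategy never
#' ordered stay `not_performed` and the WHO 2022 decision table sees exactly
#' what the strategy revealed, mirroring an investigator blinded to the
#' full-panel result.
#'
#' @param oracle A [stain_oracle()].
#' @param strategy `"gold_standard"` (or `"gold"`), or an algorithm id 1, 2
#'   or 3.
#' @param morphology A [morphology_flags()] vector.
#' @param unit_cost Cost per immunostain; default 50 (AUD).
#' @param rules PIT1 sub-table passed to [classify()].
#' @return List with elements `plan` (a `stain_plan`) and `classification`
#'   (a `who2022_classification`).
#' @examples
#' neg <- stain_oracle(ihc_profile(negative = all_markers()))
#' diagnose_with_strategy(neg, 3)$classification$type  # null_cell, 9 stains
#' @export
diagnose_with_strategy <- function(oracle, strategy,
                                   morphology = morphology_flags(),
                                   unit_cost = 50,
                                   rules = who2022_pit1_rules()) {
  plan <- if (is.character(strategy) && strategy %in% c("gold", "gold_standard")) {
    run_gold_standard(oracle, unit_cost)
  } else {
    run_tiered(oracle, as.numeric(strategy), unit_cost)
  }
  list(plan = plan,
       classification = classify(plan$observed, morphology, rules))
}

#' Enumerate all fully-performed +/- profiles
#'
#' All 2^9 = 512 profiles in which every marker is performed and called
#' positive or negative — the complete truth table over the nine-stain
#' panel, used for exhaustive oracle-equivalence audits.
#'
#' @return List of 512 [ihc_profile()] objects.
#' @export
enumerate_profiles <- function() {
  grid <- expand.grid(rep(list(c("negative", "positive")), 9),
                      stringsAsFactors = FALSE)
  names(grid) <- all_markers()
  lapply(seq_len(nrow(grid)), function(i) {
    structure(unlist(grid[i, ], use.names = TRUE), class = "ihc_profile")
  })
}

#' Exhaustive tiered-vs-gold-standard audit
#'
#' For every one of the 512 fully-performed profiles (morphology flags
#' absent), compares the diagnosis a tiered algorithm reaches from its
#' tier-limited observed profile with the full-panel gold-standard
#' diagnosis, and records which gold-standard warnings the tiered plan could
#' not have emitted because the triggering stain was never ordered — the
#' information the algorithm deliberately discards.
#'
#' @param algorithm 1, 2 or 3.
#' @return Data frame with one row per profile: `profile` (compact +/-
#'   string in canonical marker order), `n_tf_positive`, `gold_type`,
#'   `tiered_type`, `n_stains`, `concordant`, and `lost_warnings`.
#' @examples
#' aud <- audit_tiered_vs_gold(3)
#' sum(!aud$concordant)
#' @export
audit_tiered_vs_gold <- function(algorithm) {
  profiles <- enumerate_profiles()
  rows <- lapply(profiles, function(p) {
    oracle <- stain_oracle(p)
    gold <- classify(p)
    tiered <- diagnose_with_strategy(oracle, algorithm)
    lost <- setdiff(gold$warnings, tiered$classification$warnings)
    data.frame(
      profile = paste0(ifelse(p == "positive", "+", "-"), collapse = ""),
      n_tf_positive = length(gold$tf_pattern),
      gold_type = gold$type,
      tiered_type = tiered$classification$type,
      n_stains = tiered$plan$n_stains,
      concordant = gold$type == tiered$classification$type,
      lost_warnings = paste(lost, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
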