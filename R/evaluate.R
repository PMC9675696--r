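#' Evaluate tiered strategies against the gold standard
#'
#' Runs the full-panel gold standard and the requested tiered algorithms on
#' every tumour of a cohort and compares diagnoses. Concordance counts the
#' records whose tiered diagnosis equals the gold-standard diagnosis, at
#' type level by default or at lineage level (`level = "lineage"`). Every
#' record must carry a complete nine-stain profile, which serves as the
#' stain oracle for the tiered strategies.
#'
#' Reported averages are rounded half-up to one decimal; the average cost is
#' the rounded average stain count times `unit_cost`, rounded to the nearest
#' whole unit.
#'
#' @param cohort Cohort data frame with fully-performed profiles.
#' @param algorithms Subset of 1:3; default all three.
#' @param unit_cost Cost per immunostain; default 50 (AUD).
#' @param level `"type"` (default) or `"lineage"` concordance granularity.
#' @param rules PIT1 sub-table passed to [classify()].
#' @return Object of class `triage_evaluation`: list with `table` (one row
#'   per strategy: strategy, n_concordant, concordance_pct, total_stains,
#'   avg_stains, avg_cost), `discordant_ids` (per strategy), `n_tumours`,
#'   `unit_cost`, `level`.
#' @examples
#' ev <- evaluate(build_reference_cohort())
#' ev
#' @export
evaluate <- function(cohort, algorithms = 1:3, unit_cost = 50,
                     level = c("type", "lineage"),
                     rules = who2022_pit1_rules()) {
  level <- match.arg(level)
  validate_cohort(cohort)
  n <- nrow(cohort)
  if (n == 0) stop("cohort is empty", call. = FALSE)
  if (length(algorithms) > 0 && !all(algorithms %in% 1:3)) {
    stop("`algorithms` must be a subset of 1:3", call. = FALSE)
  }
  key <- function(cl) if (level == "type") cl$type else cl$lineage

  oracles <- lapply(seq_len(n), function(i) stain_oracle(row_profile(cohort, i)))
  morph <- lapply(seq_len(n), function(i) row_morphology(cohort, i))
  gold_class <- lapply(seq_len(n), function(i) {
    tryCatch(classify(oracles[[i]], morph[[i]], rules),
             error = function(e) stop(sprintf("record %s: %s", cohort$id[i],
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  gold_key <- vapply(gold_class, key, character(1))

  strategies <- c("gold_standard",
                  paste0("algorithm_", sort(algorithms), recycle0 = TRUE))
  rows <- list()
  discordant_ids <- list()
  for (s in strategies) {
    if (s == "gold_standard") {
      counts <- rep(9L, n)
      keys <- gold_key
    } else {
      alg <- as.numeric(sub("algorithm_", "", s))
      runs <- lapply(seq_len(n), function(i) {
        diagnose_with_strategy(oracles[[i]], alg, morph[[i]], unit_cost, rules)
      })
      counts <- vapply(runs, function(r) r$plan$n_stains, integer(1))
      keys <- vapply(runs, function(r) key(r$classification), character(1))
    }
    conc <- keys == gold_key
    avg <- round_half_up(sum(counts) / n, 1)
    rows[[s]] <- data.frame(
      strategy = s,
      n_concordant = sum(conc),
      concordance_pct = round_half_up(sum(conc) / n * 100, 1),
      total_stains = sum(counts),
      avg_stains = avg,
      avg_cost = round_half_up(avg * unit_cost, 0),
      stringsAsFactors = FALSE
    )
    discordant_ids[[s]] <- cohort$id[!conc]
  }
  structure(
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         discordant_ids = discordant_ids, n_tumours = n,
         unit_cost = unit_cost, level = level),
    class = "triage_evaluation"
  )
}

#' Render an evaluation as a text table
#'
#' One row per strategy with concordance, total and average stain counts and
#' average cost, in a fixed column order; the footer records the cost model
#' (average cost = rounded average stains x unit cost).
#'
#' @param report A `triage_evaluation` from [evaluate()].
#' @return Character vector of lines, invisibly printable with `cat`.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "triage_evaluation"))
  tab <- report$table
  header <- sprintf("%-14s %18s %12s %10s %10s",
                    "strategy", "concordant (%)", "total stains",
                    "avg stains", "avg cost")
  body <- sprintf("%-14s %11d (%s) %12d %10.1f %10.0f",
                  tab$strategy, tab$n_concordant,
                  formatC(tab$concordance_pct, format = "f", digits = 1),
                  tab$total_stains, tab$avg_stains, tab$avg_cost)
  gold_cost <- 9 * report$unit_cost
  reductions <- 100 * (1 - tab$avg_cost / gold_cost)
  footer <- c(
    sprintf("n = %d tumours; %s-level concordance; unit cost %g per stain",
            report$n_tumours, report$level, report$unit_cost),
    "avg cost = avg stains (rounded to 1 dp) x unit cost",
    sprintf("cost reduction vs gold standard: %s",
            paste(sprintf("%s %.1f%%", tab$strategy, reductions),
                  collapse = ", ")))
  c(header, body, "", footer)
}

#' @export
print.triage_evaluation <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' @export
summary.triage_evaluation <- function(object, ...) {
  disc <- object$discordant_ids
  n_disc <- vapply(disc, length, integer(1))
  cat(render_report(object), sep = "\n")
  if (any(n_disc > 0)) {
    cat("\ndiscordant records:\n")
    for (s in names(disc)[n_disc > 0]) {
      cat("  ", s, ": ", paste(disc[[s]], collapse = ", "), "\n", sep = "")
    }
  } else {
    cat("\nno discordant records\n")
  }
  invisible(object)
}

#' @export
as.data.frame.triage_evaluation <- function(x, ...) x$table
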