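#' Default type mixture of the synthetic generator
#'
#' Type probabilities default to the reference cohort's composition (e.g.
#' gonadotroph 45/113, lactotroph 21/113, corticotroph 14/113), and the
#' per-type probability that a tumour is clinically functioning defaults to
#' the reference cohort's functioning fractions (e.g. 10/11 for somatotroph,
#' 0/45 for gonadotroph).
#'
#' @return Named numeric vector over the 12 WHO 2022 types.
#' @export
default_type_probs <- function() {
  counts <- c(somatotroph = 11, lactotroph = 21, mammosomatotroph = 3,
              thyrotroph = 2, mature_plurihormonal_PIT1 = 1,
              immature_PIT1 = 2, acidophil_stem_cell = 0,
              mixed_somatotroph_lactotroph = 2, corticotroph = 14,
              gonadotroph = 45, plurihormonal_no_distinct_lineage = 11,
              null_cell = 1)
  counts / sum(counts)
}

#' @rdname default_type_probs
#' @export
default_functioning_probs <- function() {
  c(somatotroph = 10 / 11, lactotroph = 20 / 21, mammosomatotroph = 1,
    thyrotroph = 1 / 2, mature_plurihormonal_PIT1 = 1,
    immature_PIT1 = 1 / 2, acidophil_stem_cell = 0,
    mixed_somatotroph_lactotroph = 1 / 2, corticotroph = 10 / 14,
    gonadotroph = 0, plurihormonal_no_distinct_lineage = 6 / 11,
    null_cell = 0)
}

#' Synthetic cohort generator configuration
#'
#' Bundles and validates the parameters of [generate_cohort()]. The
#' defaults reproduce the statistical structure of the reference cohort:
#' its type mixture, its functioning fractions, and no aberrance or hormone
#' silencing.
#'
#' @param n Cohort size.
#' @param seed Integer seed; the same seed and configuration give a
#'   byte-identical cohort.
#' @param type_probs Named probability vector over the 12 WHO 2022 types;
#'   must sum to 1.
#' @param functioning_probs Named per-type probability that a tumour is
#'   clinically functioning.
#' @param aberrant_tf_rate Probability that a lineage tumour gains a
#'   spurious extra positive transcription factor (its reference type then
#'   becomes plurihormonal with no distinct lineage). Default 0.
#' @param hormone_silent_rate Probability that a lineage tumour's
#'   lineage-defining hormone stains are switched to negative while the
#'   reference type is kept — an immunohistochemically silent ("whispering")
#'   tumour. Never creates out-of-lineage positives. Default 0.
#' @param silent_types Types eligible for hormone silencing; default all.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n, seed = 1L,
                             type_probs = default_type_probs(),
                             functioning_probs = default_functioning_probs(),
                             aberrant_tf_rate = 0,
                             hormone_silent_rate = 0,
                             silent_types = names(default_type_probs())) {
  if (length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  valid_types <- setdiff(tumour_type_names(), "unclassifiable")
  unknown <- setdiff(names(type_probs), valid_types)
  if (is.null(names(type_probs)) || length(unknown) > 0) {
    stop("`type_probs` must be named by WHO 2022 type", call. = FALSE)
  }
  if (any(type_probs < 0) || abs(sum(type_probs) - 1) > 1e-9) {
    stop("`type_probs` must be non-negative and sum to 1", call. = FALSE)
  }
  for (r in c(aberrant_tf_rate, hormone_silent_rate)) {
    if (length(r) != 1 || is.na(r) || r < 0 || r > 1) {
      stop("rates must be single probabilities in [0, 1]", call. = FALSE)
    }
  }
  if (any(functioning_probs < 0 | functioning_probs > 1)) {
    stop("`functioning_probs` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 type_probs = type_probs,
                 functioning_probs = functioning_probs,
                 aberrant_tf_rate = aberrant_tf_rate,
                 hormone_silent_rate = hormone_silent_rate,
                 silent_types = silent_types),
            class = "generator_config")
}

#' Generate a synthetic cohort
#'
#' Draws `n` tumour records with the canonical profile of a type sampled
#' from `type_probs`. Each record consumes a fixed block of five draws from
#' a single seeded stream — type, functioning status, hormone silencing,
#' transcription factor aberrance, and the choice of aberrant factor — so
#' that enlarging `n` extends a cohort without reshuffling earlier records.
#' Hormone silencing turns the lineage-defining hormone stain(s) negative
#' while keeping `reference_type` (the tumour still carries its lineage
#' transcription factor); aberrance adds one extra positive transcription
#' factor and relabels `reference_type` as plurihormonal with no distinct
#' lineage, since that is what a full-panel diagnosis would conclude.
#'
#' @param config A [generator_config()].
#' @return Cohort data frame with `config$n` rows, ids `SYN-000001` ...
#' @examples
#' cohort <- generate_cohort(generator_config(n = 50, seed = 42))
#' table(cohort$reference_type)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  types <- names(config$type_probs)
  cdf <- cumsum(config$type_probs)
  tfs <- tf_markers()
  set.seed(config$seed)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    u <- stats::runif(5)
    type <- types[which(u[1] <= cdf + 1e-12)[1]]
    cc <- canonical_case(type)
    profile <- unclass(cc$profile)
    p_fun <- config$functioning_probs[type]
    functioning <- !is.na(p_fun) && u[2] < p_fun
    clinical <- if (functioning) functioning_label(type) else "non_functioning"
    ref_type <- type
    lineage <- type_lineage(type)
    if (lineage != "none") {
      if (u[3] < config$hormone_silent_rate && type %in% config$silent_types) {
        defining <- intersect(hormone_markers(),
                              names(profile)[profile == "positive"])
        profile[defining] <- "negative"
      }
      if (u[4] < config$aberrant_tf_rate) {
        extra <- setdiff(tfs, names(profile)[profile == "positive"])
        pick <- extra[ceiling(u[5] * length(extra))]
        profile[pick] <- "positive"
        ref_type <- "plurihormonal_no_distinct_lineage"
      }
    }
    recs[[i]] <- tumour_record(
      sprintf("SYN-%06d", i),
      structure(profile, class = "ihc_profile"),
      clinical = clinical, morphology = cc$morphology,
      reference_type = ref_type)
  }
  if (n == 0) {
    cohort <- build_reference_cohort()[0, , drop = FALSE]
    rownames(cohort) <- NULL
    return(cohort)
  }
  do.call(rbind, recs)
}
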