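#' Construct an IHC profile
#'
#' An IHC profile holds one tri-state result per marker: all nine slots are
#' always present, each "positive", "negative" or "not_performed". Stains a
#' tiered strategy never ordered stay `not_performed`; they are never
#' silently treated as negative.
#'
#' @param positive Character vector of markers called positive.
#' @param negative Character vector of markers called negative.
#' @param not_performed Character vector of markers not stained. Markers
#'   named in none of the three arguments default to not_performed.
#' @return Named character vector of length 9, class `ihc_profile`, in
#'   canonical marker order.
#' @examples
#' ihc_profile(positive = c("SF1", "FSH", "LH"),
#'             negative = setdiff(all_markers(), c("SF1", "FSH", "LH")))
#' @export
ihc_profile <- function(positive = character(), negative = character(),
                        not_performed = character()) {
  given <- c(positive, negative, not_performed)
  unknown <- setdiff(given, all_markers())
  if (length(unknown) > 0) {
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(given)) {
    dup <- unique(given[duplicated(given)])
    stop("marker(s) assigned more than one status: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  status <- rep("not_performed", 9)
  names(status) <- all_markers()
  status[positive] <- "positive"
  status[negative] <- "negative"
  structure(status, class = "ihc_profile")
}

# Validate an object as a 9-slot tri-state profile; returns it invisibly.
validate_profile <- function(profile) {
  if (!is.character(profile) || length(profile) != 9 ||
      !setequal(names(profile), all_markers())) {
    stop("an IHC profile must have exactly one entry per marker (",
         paste(all_markers(), collapse = ", "), ")", call. = FALSE)
  }
  bad <- !profile %in% stain_statuses()
  if (any(bad)) {
    stop("invalid stain status for ", paste(names(profile)[bad], collapse = ", "),
         ": statuses must be positive/negative/not_performed", call. = FALSE)
  }
  invisible(profile[all_markers()])
}

#' @export
print.ihc_profile <- function(x, ...) {
  sym <- c(positive = "+", negative = "-", not_performed = ".")
  cat("IHC profile: ",
      paste(names(x), sym[unname(x)], sep = "", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Parse one raw marker cell. Accepts "+", "-", the typographic minus
# U+2212 (used in published tables), a number 0-100 (binarized at
# `threshold`), or empty/NA (= not performed).
parse_marker_value <- function(x, threshold = 10) {
  if (length(x) != 1) stop("expected a single value", call. = FALSE)
  if (is.numeric(x)) {
    if (is.na(x)) return("not_performed")
    return(binarize(x, threshold))
  }
  x <- trimws(as.character(x))
  if (is.na(x) || x == "") return("not_performed")
  if (x == "+") return("positive")
  if (x %in% c("-", "−")) return("negative")
  if (x %in% stain_statuses()) return(x)
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(binarize(n, threshold))
  stop(sprintf("unparseable stain value \"%s\"", x), call. = FALSE)
}

#' Parse a raw IHC row into a profile
#'
#' Accepts a named list or vector mapping marker names to raw values as they
#' appear in laboratory spreadsheets: "+" for positive, "-" (hyphen) or the
#' typographic minus for negative, a number 0--100 for percent positive
#' cells (binarized at `threshold`), or empty for not performed. Markers
#' absent from the input become not_performed.
#'
#' @param row Named list or character vector; names must be marker names.
#' @param threshold Positivity cut-off passed to [binarize()].
#' @return An [ihc_profile()].
#' @examples
#' parse_profile(c(PIT1 = "+", SF1 = "+", PRL = "+"))
#' parse_profile(list(SF1 = 15))
#' @export
parse_profile <- function(row, threshold = 10) {
  if (length(row) == 0) return(ihc_profile())
  if (is.null(names(row)) || any(names(row) == "")) {
    stop("`row` must be fully named by marker", call. = FALSE)
  }
  unknown <- setdiff(names(row), all_markers())
  if (length(unknown) > 0) {
    stop("unknown marker name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  status <- rep("not_performed", 9)
  names(status) <- all_markers()
  for (m in names(row)) {
    status[[m]] <- tryCatch(
      parse_marker_value(row[[m]], threshold),
      error = function(e) {
        stop(sprintf("marker %s: %s", m, conditionMessage(e)), call. = FALSE)
      }
    )
  }
  structure(status, class = "ihc_profile")
}

#' Serialize a profile to raw +/- symbols
#'
#' Inverse of [parse_profile()] for pathologist-called profiles: positive
#' becomes "+", negative "-", not_performed the empty string. Round-trips
#' with [parse_profile()] for any valid profile.
#'
#' @param profile An [ihc_profile()].
#' @return Named character vector over the 9 markers.
#' @export
serialize_profile <- function(profile) {
  validate_profile(profile)
  sym <- c(positive = "+", negative = "-", not_performed = "")
  out <- sym[unname(profile[all_markers()])]
  names(out) <- all_markers()
  out
}

#' Morphology flags
#'
#' Optional histology flags that refine PIT1-lineage typing. Each is TRUE,
#' FALSE or NA (unknown); the underlying H&E/ultrastructural assessment is
#' outside the scope of this package, so the flags are taken as given.
#'
#' @param monomorphous Single tumour cell population co-expressing GH and
#'   PRL (mammosomatotroph) vs two populations (mixed somatotroph and
#'   lactotroph).
#' @param immature Immature PIT1-lineage histology.
#' @param acidophil_stem_cell_features Acidophil stem cell histology.
#' @return Named logical vector of length 3.
#' @export
morphology_flags <- function(monomorphous = NA, immature = NA,
                             acidophil_stem_cell_features = NA) {
  out <- c(monomorphous = as.logical(monomorphous),
           immature = as.logical(immature),
           acidophil_stem_cell_features = as.logical(acidophil_stem_cell_features))
  if (length(out) != 3) stop("flags must be single logicals", call. = FALSE)
  out
}

# Recognised clinical presentation labels. Clinical presentation is carried
# for reporting and warnings only; the classifier branches on IHC alone.
clinical_labels <- function() {
  c("non_functioning", "acromegaly", "prolactinoma", "cushing",
    "thyrotoxicosis", "other")
}

#' Build a single tumour record
#'
#' A tumour record is one row of a cohort data frame: an id, a clinical
#' presentation, the nine tri-state marker statuses, the three optional
#' morphology flags, and an optional known reference type.
#'
#' @param id Record identifier, unique within a cohort.
#' @param profile An [ihc_profile()].
#' @param clinical One of non_functioning, acromegaly, prolactinoma,
#'   cushing, thyrotoxicosis, other.
#' @param morphology A [morphology_flags()] vector.
#' @param reference_type Optional known WHO 2022 type name, or NA.
#' @return One-row data frame in cohort layout.
#' @examples
#' tumour_record("case-1",
#'   ihc_profile(positive = c("SF1", "FSH"),
#'               negative = setdiff(all_markers(), c("SF1", "FSH"))))
#' @export
tumour_record <- function(id, profile, clinical = "non_functioning",
                          morphology = morphology_flags(),
                          reference_type = NA_character_) {
  validate_profile(profile)
  clinical <- match.arg(clinical, clinical_labels())
  if (!is.na(reference_type)) {
    reference_type <- match.arg(reference_type, tumour_type_names())
  }
  rec <- data.frame(id = as.character(id), clinical = clinical,
                    stringsAsFactors = FALSE)
  for (m in all_markers()) rec[[m]] <- unname(profile[[m]])
  rec$monomorphous <- unname(morphology[["monomorphous"]])
  rec$immature <- unname(morphology[["immature"]])
  rec$acidophil_stem_cell_features <-
    unname(morphology[["acidophil_stem_cell_features"]])
  rec$reference_type <- reference_type
  rec
}

# Extract the profile / morphology of row i of a cohort data frame.
row_profile <- function(cohort, i) {
  status <- vapply(all_markers(), function(m) cohort[[m]][i], character(1))
  structure(status, class = "ihc_profile")
}

row_morphology <- function(cohort, i) {
  morphology_flags(cohort$monomorphous[i], cohort$immature[i],
                   cohort$acidophil_stem_cell_features[i])
}
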