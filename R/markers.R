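#' Marker panels
#'
#' The nine immunostains used for WHO 2022 type diagnosis of pituitary
#' neuroendocrine tumours: three lineage-determining transcription factors
#' and six anterior pituitary hormones. The order returned is the canonical
#' staining order used throughout the package (transcription factors first,
#' then hormones in slide-tray order), so that stain plans are reproducible.
#'
#' @return Character vector of marker names.
#' @examples
#' tf_markers()
#' hormone_markers()
#' @export
tf_markers <- function() c("SF1", "TPIT", "PIT1")

#' @rdname tf_markers
#' @export
hormone_markers <- function() c("PRL", "TSH", "GH", "ACTH", "LH", "FSH")

#' @rdname tf_markers
#' @export
all_markers <- function() c(tf_markers(), hormone_markers())

#' Lineage of each hormone
#'
#' Maps each anterior pituitary hormone to the transcription factor that
#' drives its producing cell lineage: GH, PRL and TSH to PIT1; ACTH to TPIT;
#' LH and FSH to SF1.
#'
#' @return Named character vector, names are hormones, values transcription
#'   factors.
#' @examples
#' hormone_lineage()[["ACTH"]]
#' @export
hormone_lineage <- function() {
  c(PRL = "PIT1", TSH = "PIT1", GH = "PIT1",
    ACTH = "TPIT", LH = "SF1", FSH = "SF1")
}

#' Hormones belonging to a lineage
#'
#' @param tf One of "SF1", "TPIT", "PIT1".
#' @return Character vector of hormone names, in canonical stain order.
#' @examples
#' lineage_hormones("PIT1")
#' @export
lineage_hormones <- function(tf) {
  tf <- match.arg(tf, tf_markers())
  hl <- hormone_lineage()
  names(hl)[hl == tf]
}

# Valid tri-state stain statuses. not_performed is mandatory and distinct
# from negative: tiered algorithms deliberately leave stains unperformed and
# downstream code must never conflate the two.
stain_statuses <- function() c("positive", "negative", "not_performed")

#' Binarize a percent-positive-cells reading
#'
#' Converts a percentage of immunopositive cells into a positive/negative
#' call. A stain is called positive when at least `threshold` percent of
#' cells stain (the clinical convention for transcription factor IHC is a
#' 10\% cut-off, applied here to hormones as well when percentages are
#' supplied).
#'
#' @param percent Numeric vector of percentages in \[0, 100\].
#' @param threshold Positivity cut-off in percent, in (0, 100\]. Default 10.
#' @return Character vector, "positive" or "negative".
#' @examples
#' binarize(c(0, 9.99, 10, 85))
#' @export
binarize <- function(percent, threshold = 10) {
  if (!is.numeric(percent) || anyNA(percent)) {
    stop("`percent` must be numeric with no missing values", call. = FALSE)
  }
  if (any(percent < 0 | percent > 100)) {
    bad <- percent[percent < 0 | percent > 100][1]
    stop(sprintf("percent-positive-cells value %s is outside [0, 100]", bad),
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 100) {
    stop("`threshold` must be a single number in (0, 100]", call. = FALSE)
  }
  ifelse(percent >= threshold, "positive", "negative")
}

# Round half away from zero, the convention used for all reported
# percentages and averages (base round() is round-half-even). The small
# epsilon guards against values like 2.65 stored as 2.64999...
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
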