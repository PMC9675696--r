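# Build a fully-performed oracle positive exactly for `pos`.
oracle_with <- function(pos = character()) {
  stain_oracle(ihc_profile(positive = pos,
                           negative = setdiff(all_markers(), pos)))
}

# A random tri-state profile (used for round-trip properties).
random_profile <- function() {
  status <- sample(c("positive", "negative", "not_performed"), 9,
                   replace = TRUE)
  names(status) <- all_markers()
  structure(status, class = "ihc_profile")
}
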