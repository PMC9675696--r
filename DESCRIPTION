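Package: pittriage
Title: Tiered Transcription-Factor-First Typing of Pituitary Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rule-based typing of pituitary neuroendocrine tumours under the
    WHO 2022 classification from transcription factor (SF1, TPIT, PIT1) and
    anterior pituitary hormone immunohistochemistry, together with tiered
    (reflex) staining strategies that order hormone stains conditionally on
    the transcription factor panel. Includes a deterministic WHO 2022
    decision table, three tiered staining algorithms, cohort-level
    concordance and cost evaluation against the full nine-stain gold
    standard, a packaged reconstruction of a 113-tumour reference cohort,
    and a seeded synthetic cohort generator for testing at any scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
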