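---
title: "Tiered transcription-factor-first typing of pituitary tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered transcription-factor-first typing of pituitary tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pittriage)
```

## The problem

The WHO 2022 classification types pituitary neuroendocrine tumours by cell
lineage, established with transcription factor immunohistochemistry (IHC):
SF1 marks the gonadotroph lineage, TPIT the corticotroph lineage, and PIT1
the somatotroph/lactotroph/thyrotroph lineage. Together with six anterior
pituitary hormone stains (PRL, TSH, GH, ACTH, LH, FSH), the full diagnostic
panel comprises nine immunostains per tumour. At roughly $50 (AUD) per
immunostain, routinely staining everything costs $450 per case and loads
pathology laboratories with slides that often add no diagnostic
information: a tumour that is positive for SF1 alone is a gonadotroph
whatever its hormone stains show.

`pittriage` implements the full WHO 2022 decision table as a deterministic,
auditable classifier, plus three *tiered* (reflex) staining strategies that
order the transcription factor panel first and reflex to hormone stains
only where they can change the diagnosis. It evaluates each strategy
against the full-panel gold standard on a packaged 113-tumour reference
cohort and on seeded synthetic cohorts of any size, reporting concordance,
stain counts and cost.

## The WHO 2022 decision table

`classify()` maps a nine-slot tri-state IHC profile (each stain positive,
negative, or not performed) and three optional morphology flags to one of
the twelve WHO 2022 types, or to an `unclassifiable` sentinel when a stain
the fired branch needs was never performed. With `T` the number of positive
transcription factors, the rules fire in order:

1. `T = 0`, any hormone positive → **plurihormonal, no distinct lineage**.
2. `T = 0`, all six hormones performed and negative → **null cell**.
   Null cell is a diagnosis of exclusion: with any hormone unperformed the
   verdict is `unclassifiable`, never null cell.
3. `T ≥ 2` → **plurihormonal, no distinct lineage**.
4. `T = 1`, SF1 → **gonadotroph**; `T = 1`, TPIT → **corticotroph**.
   Hormone results never alter a single-TF type; an out-of-lineage positive
   hormone (say GH in an SF1-only tumour) raises a warning instead. A
   TPIT+/ACTH− profile additionally warns that the corticotroph is
   hormonally silent ("whispering").
5. `T = 1`, PIT1 → the (GH, PRL, TSH) sub-table, which requires those three
   stains: one positive hormone gives somatotroph, lactotroph or
   thyrotroph; GH+PRL+ splits on the `monomorphous` flag into
   mammosomatotroph (one cell population) versus mixed
   somatotroph–lactotroph (two); any other multi-hormone pattern is mature
   plurihormonal PIT1-lineage; `immature = TRUE` or
   `acidophil_stem_cell_features = TRUE` override the hormone pattern.

The PIT1 sub-table is shipped as an editable CSV
(`who2022_pit1_rules.csv`), matched top to bottom with first-match-wins
semantics, and every classification carries the ordered list of fired rule
ids so a verdict can be audited line by line. Two of its rows are
conventions rather than settled criteria, because the distinguishing
histology is outside this package's scope:

* **GH+PRL+ with the `monomorphous` flag unknown** is called
  mammosomatotroph with a warning. Mammosomatotrophs are the more common of
  the two GH+PRL+ types, and a warned default keeps the classifier total;
  an auditor who disagrees can flip one row of the rules file (a unit test
  exercises exactly this edit).
* **A hormone-silent PIT1-only tumour** (GH−PRL−TSH−) is called immature
  PIT1-lineage with a warning: among WHO 2022 types that is the one
  compatible with a committed PIT1 lineage and absent hormone expression.

Clinical presentation (non-functioning, acromegaly, prolactinoma, Cushing,
…) is deliberately **not** an input to `classify()`: the decision table
branches on IHC alone, and clinical labels travel on records for reporting
and for the functioning/non-functioning column of cohort summaries.

## Tiered staining strategies

A `stain_oracle()` holds a tumour's true nine-stain results; a strategy
reveals only what it orders. Tier 1 always orders SF1, TPIT, PIT1. With
zero or multiple positive transcription factors every strategy reflexes to
the complete hormone panel (9 stains). With exactly one:

| TF pattern | Algorithm 1 | Algorithm 2 | Algorithm 3 |
|------------|-------------|-------------|-------------|
| SF1 only   | + LH, FSH (5) | nothing (3) | nothing (3) |
| TPIT only  | + ACTH (4)    | nothing (3) | nothing (3) |
| PIT1 only  | all 6 hormones (9) | all 6 hormones (9) | GH, PRL, TSH (6) |

Algorithm 1's single-TF branches order the lineage-confirmatory hormones;
its exact second-tier rules were genuinely open when this package was
designed, so they live in code behind the same `run_tiered()` surface and
the lineage-confirmatory reading was adopted because it is the natural
intermediate between the full panel and Algorithms 2–3 and reproduces the
reference cohort's per-strategy stain averages. Tiers are batched rounds —
all tier-1 results are read before tier 2 is chosen — mirroring laboratory
batching; there is no stain-by-stain adaptivity. Stains within a tier
follow a fixed canonical order (SF1, TPIT, PIT1; PRL, TSH, GH, ACTH, LH,
FSH) so plans are byte-for-byte reproducible; cost is order-independent.

`diagnose_with_strategy()` classifies from the tier-limited observed
profile only, with unordered stains left `not_performed`, mirroring an
investigator blinded to the full panel. An exhaustive audit over all
2^9 = 512 fully-performed profiles (`audit_tiered_vs_gold()`) shows that
under the rules above the tiered diagnosis never diverges from the gold
standard at type level: the only information a tiered plan discards is
warning-grade (out-of-lineage hormone positivity and hormonal silence in
single-TF tumours), which the audit surfaces in a `lost_warnings` column.
That equivalence is a property of rule 4 treating out-of-lineage hormones
as warnings; a rule set that escalated them to a type change would make
exactly those single-TF profiles discordant.

## Cost model and evaluation

`evaluate()` compares strategies on a cohort whose records carry complete
profiles (the oracles). Concordance is the share of records where the
tiered type equals the gold-standard type; a lineage-level mode
(`level = "lineage"`) is also available because concordance granularity is
a genuine reporting choice. Averages are rounded half away from zero to
one decimal, and the average cost is defined as the *rounded* average
stain count × unit cost (so 4.8 average stains at $50 gives exactly $240);
this relation is printed in the report footer. The gold standard always
costs 9 × unit cost, and per-tumour dominance (Alg 3 ≤ Alg 2 ≤ Alg 1 ≤ 9
stains) makes the cost ordering monotone on any cohort.

## The reference cohort reconstruction

`build_reference_cohort()` assembles 113 records: the 12 no-distinct-
lineage cases transcribed stain-for-stain from the published case table
(shipped verbatim in `table3_profiles.csv`, typographic minus signs
included), and 101 distinct-lineage records — 45 gonadotroph, 14
corticotroph, 42 PIT1-lineage across eight types — with type counts and
clinically-functioning counts matching the published type table. Per-case
hormone profiles of the 101 lineage tumours were not published, so each
carries the *canonical* profile for its type: positive for its
transcription factor and defining hormone(s), negative elsewhere (e.g.
SF1+LH+FSH+ for gonadotroph). Tiered stain counts depend only on the
transcription factor pattern, which the lineage fixes, so this convention
cannot move concordance or cost results; it does make the reconstruction's
raw stain totals (767/663/537 for Algorithms 1–3) sit a few stains below
the totals of the real cohort, whose handful of unpublished
multi-transcription-factor profiles are not fabricated here. The
one-decimal averages (6.8/5.9/4.8) are invariant to that gap and are the
reproduction surface. Functioning records take the obvious presentation
for their type (acromegaly for GH-expressing PIT1 types and, by
convention, for the hormone-negative immature PIT1 type; prolactinoma for
lactotroph; Cushing for corticotroph; "other" for thyrotroph).

## The synthetic generator

`generate_cohort()` emulates cohorts with the reference study's
statistical structure: types drawn from the reference mixture (gonadotroph
45/113, lactotroph 21/113, corticotroph 14/113, …), functioning status
from per-type fractions (10/11 for somatotroph, 0/45 for gonadotroph), and
canonical profiles per type. Two default-off noise knobs probe robustness:

* `hormone_silent_rate` switches a lineage tumour's defining hormone
  stains to negative while keeping its transcription factor and reference
  type — the immunohistochemically silent ("whispering") tumour. It never
  creates out-of-lineage positives, and restricted to corticotrophs it
  demonstrates the core robustness argument for transcription-factor-first
  testing: tiered concordance stays at 100% while ACTH positivity drops.
* `aberrant_tf_rate` adds one spurious extra positive transcription
  factor and relabels the reference type plurihormonal, since that is what
  a full-panel reading of the profile concludes; such cases reflex to the
  full panel in every tiered algorithm, so concordance again survives.
  Out-of-lineage *hormone* aberrance — the one mechanism that could break
  tiered/gold type concordance under an escalating rule set — is
  deliberately not generated by default.

Each record consumes a fixed block of five draws (type, functioning,
silencing, aberrance, aberrant-factor choice) from one seeded stream, so
the same seed yields a byte-identical cohort and enlarging `n` extends a
cohort without reshuffling earlier records. The generator emulates
composition and these two noise mechanisms only: it does not model
percent-positive-cell distributions, borderline staining near the 10%
cut-off, inter-observer variation, tumour size or biochemistry. Passing
tests on synthetic cohorts therefore certify the decision logic and
bookkeeping, not the behaviour of the rules on borderline real-world
staining.

## Numerical and input conventions

* Percent-positive-cells readings binarize with an **inclusive** threshold
  (≥ 10% is positive by default, configurable); the same rule applies to
  hormones when percentages are supplied, while pathologist-called "+"/"−"
  values pass through untouched. Monotonicity in the percentage is tested.
* All reported percentages and averages round half away from zero (one
  decimal), with a 1e-9 guard against representation error; costs round to
  the whole unit.
* Marker cells accept "+", "-" (hyphen) and "−" (typographic minus, as
  published case tables use), a number 0–100, or empty (= not performed);
  `not_performed` is a first-class state and is never silently read as
  negative.
* The CSV round trip `read_cohort(write_cohort(x))` is lossless, including
  unperformed stains and unknown flags; readers name the row and column of
  any malformed cell.

## Test problem sizes

The suite exercises the exhaustive 512-profile truth table for the
classifier and all three strategies, synthetic cohorts of 250–1000 records
for mixture calibration, parameter recovery and the whispering-tumour
property, and the 113-record reference cohort for the composition and cost
results; these sizes give stable stochastic checks (3-standard-error
bounds at n = 1000) while keeping the whole suite fast.

## Limitations

Granulation subtypes, proliferation markers (Ki67, mitoses), cytokeratin
patterns, reticulin, prognosis and metastasis criteria are out of scope;
morphology enters only as the three boolean flags. The classifier encodes
one defensible reading of the WHO 2022 type definitions where those
definitions leave room (the flag-unknown and hormone-silent PIT1 rows),
and the reference cohort's 101 lineage profiles are canonical
reconstructions, not the original per-case data.
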