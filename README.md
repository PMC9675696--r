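# pittriage

Tiered, transcription-factor-first typing of pituitary neuroendocrine
tumours under the WHO 2022 classification, with concordance and cost
evaluation of reflex staining strategies.

## The problem

WHO 2022 types pituitary tumours by cell lineage, established by
transcription factor immunohistochemistry (IHC): **SF1** → gonadotroph,
**TPIT** → corticotroph, **PIT1** → somatotroph / lactotroph / thyrotroph.
The full diagnostic panel adds six hormone stains (PRL, TSH, GH, ACTH, LH,
FSH) for nine immunostains per tumour — about $450 (AUD) at $50 per stain —
although for many tumours the hormone stains cannot change the diagnosis:
an SF1-only tumour is a gonadotroph whatever its hormones show.

`pittriage` is for pathologists, endocrinologists and biostatisticians who
want to (a) type tumours deterministically and auditably from IHC profiles,
and (b) quantify what a tiered (reflex) staining strategy saves and whether
it ever changes a diagnosis.

## The model

A tumour's profile is nine tri-state stain results (positive / negative /
not performed; a stain is positive when ≥ 10% of cells stain). With `T` the
number of positive transcription factors, the WHO 2022 decision table is:

* `T = 0`: any hormone positive → *plurihormonal, no distinct lineage*;
  all six hormones negative → *null cell* (a diagnosis of exclusion).
* `T ≥ 2`: *plurihormonal, no distinct lineage*.
* `T = 1`: SF1 → *gonadotroph*; TPIT → *corticotroph* (out-of-lineage
  hormone positivity warns, never re-types); PIT1 → a (GH, PRL, TSH)
  sub-table resolving the eight PIT1-lineage types, shipped as an editable
  rules file.

Three tiered strategies stain SF1/TPIT/PIT1 first and reflex to the full
hormone panel when `T ≠ 1`. For single-TF tumours: Algorithm 1 adds the
lineage-confirmatory hormones (LH/FSH after SF1, ACTH after TPIT, all six
after PIT1); Algorithm 2 adds hormones only after PIT1; Algorithm 3 adds
only GH/PRL/TSH after PIT1. Evaluation reports, per strategy, concordance
with the nine-stain gold standard, total/average stains, and average cost
(rounded average stains × unit cost).

## Worked example

```r
library(pittriage)

# A percentage is binarized at the 10% cut-off; 85% SF1 is positive.
classify(parse_profile(c(SF1 = "85", TPIT = "-", PIT1 = "-")))
#> WHO 2022 type: gonadotroph (lineage: SF1)
#>   positive TFs: SF1
#>   rules fired:  TF_COUNT=1 -> TF1_SF1_GONADOTROPH
```

The fired rule ids make every verdict auditable. Staining a PIT1+ GH+ PRL+
tumour with Algorithm 3 orders six stains instead of nine:

```r
oracle <- stain_oracle(parse_profile(c(
  SF1 = "-", TPIT = "-", PIT1 = "+", PRL = "+", TSH = "-",
  GH = "+", ACTH = "-", LH = "-", FSH = "-")))
d <- diagnose_with_strategy(oracle, 3)
d$plan
#> Stain plan [algorithm_3]: 6 stains, cost 300 (50/stain)
#>   ordered: SF1, TPIT, PIT1, PRL, TSH, GH
d$classification
#> WHO 2022 type: mammosomatotroph (lineage: PIT1)
#>   positive TFs: PIT1
#>   rules fired:  TF_COUNT=1 -> TF1_PIT1_SUBTABLE -> PIT1_GH_PRL_FLAG_UNKNOWN
#>   warning: monomorphous flag unknown; mammosomatotroph assumed over mixed somatotroph-lactotroph
```

The GH+PRL+ pattern needs the `monomorphous` morphology flag to separate
mammosomatotroph from mixed somatotroph–lactotroph; with the flag unknown
the call defaults to mammosomatotroph and says so.

Evaluating all strategies on the packaged 113-tumour reference cohort:

```r
evaluate(build_reference_cohort())
#> strategy           concordant (%) total stains avg stains   avg cost
#> gold_standard          113 (100.0)         1017        9.0        450
#> algorithm_1            113 (100.0)          767        6.8        340
#> algorithm_2            113 (100.0)          663        5.9        295
#> algorithm_3            113 (100.0)          537        4.8        240
#>
#> n = 113 tumours; type-level concordance; unit cost 50 per stain
#> avg cost = avg stains (rounded to 1 dp) x unit cost
#> cost reduction vs gold standard: gold_standard 0.0%, algorithm_1 24.4%, algorithm_2 34.4%, algorithm_3 46.7%
```

Every tiered algorithm reaches the gold-standard type for all 113 tumours;
Algorithm 3 averages 4.8 stains ($240) against the gold standard's 9
($450). Synthetic cohorts of any size, with optional "whispering" (hormone-
silent) and aberrant-transcription-factor noise, come from
`generate_cohort(generator_config(n = 500, seed = 42))`; a thin command-line
front end lives at `inst/cli/triage.R`.

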