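# phytoscreen

Tools for early-stage screening of plant extracts as cosmetic active
ingredients. The package covers the whole desk side of a screening
campaign:

- **Microplate bioassay processing** — 96-well plate reads for DPPH radical
  scavenging and hyaluronidase, tyrosinase, lipoxygenase and collagenase
  inhibition. Each well is read twice; the corrected OD is
  `OD_first − OD_second`. Inhibition is computed either control-referenced,
  `%I = (OD_control − OD_sample) / OD_control × 100` (DPPH, tyrosinase,
  lipoxygenase), or blank-referenced (hyaluronidase, collagenase), with
  both published parses of the blank-referenced expression available.
  Technical replicates are summarised as mean, sample SD and
  SEM = SD/√n (N = 3 by convention).
- **Quantification** — ordinary least-squares calibration curves express
  FRAP as µg Fe²⁺ equivalents per mg dry extract (FeSO₄·7H₂O standards,
  elemental-iron molar mass 55.845 g/mol) and total phenolic content as
  mg gallic acid equivalents per g dry extract; `percent_change()` compares
  cultivation conditions.
- **Scoring** — inhibition percentages map to plus-grades by 20-point bins
  (`−` below 20 up to `++++` at 80 and above, boundaries in the upper bin).
  An extract's bioactivity score is
  `100 × Σ points / (4 × number of determined assays)` (so `n.d.` assays
  shrink the denominator), a species' score is the mean of its extracts'
  scores, and the innovation score normalizes three 0–3 expert sub-scores
  (market, patent, literature) to `100 × total / 9`. All rounding is
  half-up: one decimal for extract scores, integers elsewhere.
- **Prioritization** — species are placed in the bioactivity × innovation
  plane; those with innovation ≥ 60 and bioactivity ≥ 40 (inclusive) form
  the shortlist.
- **Funnel filter** — an ordered rule engine over candidate registries
  (regulatory, conservation, distribution and feasibility attributes) with
  per-stage counts and a per-record audit trail.
- **Synthetic data** — plates with known true inhibition and registries
  with prescribed per-stage retention, so every stage is testable without
  instrument files or database access.

The printed tables of the screening study (grades and scores for 18
species, innovation rubric, cultivation readouts) ship as plain CSV and are
accessible through `screening_grades()`, `innovation_rubric()` and
`cultivation_results()`.

## Worked example

```r
library(phytoscreen)

# one extract graded over five assays, hyaluronidase not determined
extract_bioactivity_score(c("++++", "n.d.", "-", "++", "-"))
#> [1] 37.5

# rubric sub-scores: strong market and patent novelty, documented literature
innovation_score(3, 3, 1)
#> [1] 78

# full screening panel -> dual-score shortlist
res <- run_pipeline(screening_grades(), innovation_rubric())
res$shortlist
#> [1] "Cormus domestica" "Clematis vitalba" "Corylus avellana" "Primula veris"
```

The scorer warns about grade rows whose printed scores are internally
inconsistent with their printed grades (two reference rows, one Narcissus
jonquilla extract and one Corylus avellana extract); computed values follow
the stated rule and the printed rows are kept as shipped.

The numbered scripts under `analysis/` run the four analyses end to end and
write their tables under `results/`: `01_screening_scores.R` (scores,
scatter export, shortlist), `02_selection_funnel.R` (funnel engine against
the study's retention sequence 1614 → 1532 → 1509 → 415 → 415 → 177 → 64 →
18 on a synthetic registry), `03_cultivation_response.R` (percent changes
across cultivation conditions, e.g. FRAP +95 % and TPC +17 % under reduced
temperature), and `04_assay_simulation.R` (parameter recovery on simulated
plates).

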