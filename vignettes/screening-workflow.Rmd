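---
title: "Methods: plate assays, dual scoring and the selection funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate assays, dual scoring and the selection funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoscreen)
```

This vignette documents the models and conventions behind phytoscreen: how
plate reads become inhibition percentages, how those become scores and a
shortlist, how the candidate funnel is modelled, and what the synthetic-data
generators do and do not emulate.

## Plate assays

Every well is read twice — before and after the colour (or turbidity)
reaction — and the corrected OD is the difference `OD_first − OD_second`.
The sign is preserved deliberately: a well whose absorbance rises gives a
negative corrected OD, and downstream inhibition values may be negative or
exceed 100 %. No clamping happens at the computation layer; values only
saturate at the grading step, where everything below 20 % is `−` and
everything at or above 80 % is `++++`. This keeps the raw data intact for
quality control.

Two inhibition formulas are used, following assay chemistry:

* **Control-referenced** (DPPH, tyrosinase, lipoxygenase):
  `%I = (OD_control − OD_sample) / OD_control × 100`. The control is the
  uninhibited reaction; signal loss is inhibition.
* **Blank-referenced** (hyaluronidase, collagenase): the reaction is read
  against an enzyme-free blank. The published expression for this case is
  typographically collapsed and admits two readings, and the package
  implements both: the literal parse
  `%I = OD_sample / (OD_blank − OD_control) × 100` (the default) and the
  conventional normalized form
  `%I = (OD_sample − OD_control) / (OD_blank − OD_control) × 100`
  (`variant = "normalized"`). Neither is asserted to be the intended one;
  the choice is a documented configuration switch, and the zero-noise
  simulation round-trip holds for both.

Controls and blanks are averaged per plate before use. Replicates are
technical (three wells pipetted from the same extract solution) and are
summarised as mean, sample SD (n − 1 denominator) and SEM = SD/√n. With a
single replicate the SD is undefined; it is reported as 0 with an explicit
`sd_defined = FALSE` flag rather than `NA`, and the SEM as 0. Reporting
conventions in the field vary between mean ± SEM and mean ± SD; the package
returns both so either can be quoted.

Screening is single-concentration (100 µg extract/mL in the well) by
design: it ranks species, it does not estimate IC50s.

## Calibration and units

FRAP and TPC are expressed in equivalent units via ordinary least-squares
calibration lines (`stats::lm` underneath): Fe²⁺ equivalents from
FeSO₄·7H₂O standards over 0.09–1.2 mM, gallic acid equivalents over
12.5–1000 µg/mL. Inverting the line outside the calibrated range does not
fail — extrapolated values are returned with an `in_range = FALSE` flag,
which matches how plate QC is actually done.

Conversion to a dry-weight basis uses only the known extract concentration
in the well (100 µg/mL): equivalents per volume divided by extract mass per
volume, so any common dilution factor cancels. Fe²⁺ equivalents use the
molar mass of **elemental iron** (55.845 g/mol), not the heptahydrate —
the output unit is µg Fe per mg dry extract. One worked consequence:
1 mM Fe²⁺ well-equivalent is 55.845 µg Fe/mL over 0.1 mg extract/mL, i.e.
558.45 µg Fe/mg DW. Uncertainty on these values is replicate-only; the
calibration fit's own uncertainty is not propagated.

## Grading and scores

Plus-grades are 20-point bins of percent inhibition. The published bin
definition uses strict inequalities on both sides, which leaves 20, 40, 60
and 80 formally unassigned; the package closes bins on the left
(`[20, 40) → +` and so on), which is deterministic and consistent with the
observed grading of values like 40.3 % → `++`. Grading applies to the
replicate mean, not per replicate.

The extract bioactivity score is `100 × Σ points / (4 × determined
assays)`, rounded half-up to one decimal. `n.d.` (not determined) assays
are excluded from numerator *and* denominator — an extract tested in three
assays is scored out of 12, not 20, so missing assays do not read as
inactivity. The species score is the mean of its extracts' (one-decimal)
scores, rounded half-up to an integer; a single-extract species passes its
score through. The innovation score is `100 × (market + patent +
literature) / 9`, rounded half-up, which makes exactly ten values
attainable: 0, 11, 22, 33, 44, 56, 67, 78, 89, 100. Half-up rounding
(implemented in `round_half_up()`, since base R rounds ties to even) is
what reproduces printed values like 37.5, 43.8 and 56.

The bundled grade table contains four rows whose printed scores do not
follow the stated rule: the two assay-reference rows (printed 80 and 85
where the rule gives 85 and 95 — the basis used for grading references is
not documented), one Narcissus jonquilla extract (printed 5 where the
variable-denominator rule gives 6.3, consistent instead with a fixed /20
denominator), and one Corylus avellana extract whose printed grades sum to
55 against a printed score of 60 (the printed grades and the printed score
cannot both be right; a `++++` DPPH grade would reconcile them). The
scorer computes by the rule and emits one warning per inconsistent row; it
never silently adopts a printed value.

## Prioritization

Species are classified into quadrants of the bioactivity × innovation
plane. Thresholds default to innovation ≥ 60 and bioactivity ≥ 40 and are
*inclusive* on both axes — a species at exactly 40 bioactivity is
shortlisted, which is the behaviour observed in the study's own shortlist.
The shortlist is ordered by innovation (descending), then bioactivity
(descending), then species name; the ordering is a determinism choice, as
no canonical order is defined for the shortlist itself.

## The selection funnel

The funnel is a generic ordered rule engine: each stage is a declarative
keep-predicate over candidate attributes (`flag_equals`, `in_set`,
`ordinal_at_least`, combined with `pred_all`/`pred_any`/`pred_not`), each
record is dropped at its first failing stage, and the report carries
per-stage in/out counts plus an exhaustive audit trail (every record is
retained or has exactly one first-drop stage). The default rule set mirrors
the study's seven stages — EU regulatory exclusion, CITES appendices,
presence in mainland France, INPN protection, distribution class at least
"common", bibliographic innovation review, and supply-chain feasibility
excluding invasive species. Two modelling choices are worth stating:

* Stages that the study performed manually (the bibliographic review, the
  supply-chain assessment) are modelled as expert-provided boolean
  attributes, not computed — the engine replays decisions, it does not make
  them. Likewise the engine never queries IECIC, CosIng, CITES, IUCN or
  INPN; memberships are input attributes.
* Unknown attribute values follow a configurable policy, defaulting to
  conservative drop (precautionary exclusion), with permissive-keep and
  strict-error alternatives. A stage may legitimately remove nothing (the
  INPN stage in the study kept all 415 candidates) and is still modelled as
  a real stage.

Whether "uncommon" species belong below the distribution cut is not fully
specified in the source material; the default rule keeps only common and
very common, and the ordinal predicate makes the cut configurable.

## Synthetic data

`generate_plate()` inverts the chosen inhibition formula at a requested
true inhibition and adds Gaussian noise on the corrected OD of every
measured well (samples, controls and blanks); the pair of reads is
reconstructed with the second read fixed at a baseline constant, because
the corrected difference is the only quantity downstream code consumes.
Defaults emulate the screening conditions: three technical replicates and
an additive noise SD of 0.01 AU on corrected ODs of order 1 AU, a noise
scale consistent with the sub-percent SEMs typical of the screening
readouts. With zero noise the round trip through `process_plate()` is exact
to 1e−9 for both formula variants, which is the backbone of the test suite.
The generator does not emulate plate spatial effects, drift, enzyme
kinetics, or extract chemistry — passing tests certify the computation
chain, not instrument behaviour.

`generate_registry()` constructs attribute assignments so the funnel
reproduces a prescribed retention sequence exactly (records that must fail
at stage *i* sample passing values for all earlier stages and a failing
value at *i*), then shuffles record order. It is used to exercise the
engine against the study's sequence 1614 → 1532 → 1509 → 415 → 415 → 177 →
64 → 18; reproducing those counts validates the engine's bookkeeping, not
the underlying databases, whose live contents are out of scope.

## Numerical choices and problem sizes

Ties round half away from zero throughout, with a 1e−9 guard against
binary-representation artifacts just below a tie. The calibration fitter
refuses slopes below 1e−12 in magnitude as degenerate. Property-style
tests run at fixed seeds with sizes chosen to finish in seconds while
giving the asserted bounds comfortable margin: 10,000 extracts for score
monotonicity, 1,000 simulated plates for estimator bias (asserted within
0.5 percentage points of truth at noise SD 0.01), 200 plates per condition
in the recovery analysis script, and the full 1,614-record registry for
the funnel check.

## Limitations

Bioactivity scores summarise technical replicates of one extraction per
species; they carry no biological replication and no uncertainty
propagation into the grade bins. The innovation rubric is expert input —
the package validates and normalizes it but cannot audit its derivation.
The blank-referenced formula ambiguity is exposed, not resolved. And the
funnel replays documented membership decisions; it is not a substitute for
consulting the regulatory and conservation sources themselves.
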