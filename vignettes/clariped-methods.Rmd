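---
title: "Methods: two-step pediatric triage, its statistics, and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step pediatric triage, its statistics, and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clariped)
```

## The classification procedure

The package implements a two-step risk classification for pediatric
emergency visits. Step 1 scores four vital signs — respiratory rate (RR),
heart rate (HR), oxygen saturation (SpO2), axillary temperature (AxT) —
against age-stratified band tables. RR, HR and SpO2 each receive a sub-score
0–4; the VIPE total is their sum minus a fever correction applied only when
the heart rate is elevated (HR sub-score ≥ 2): −1 for AxT 37.5–38.5 °C
(both ends inclusive), −2 above 38.5 °C. The total, clamped at zero, maps to
an urgency color (0 BLUE, 1–2 GREEN, 3–5 YELLOW, 6–9 ORANGE, ≥10 RED).
Step 2 evaluates a catalog of discriminators: five mandatory general
families (appearance, pain, fever report, newborn age, ED returns) plus
complaint-specific entries grouped by organ system. The final level is the
maximum of the VIPE color and every triggered discriminator level — the
upgrade-only rule. Each level carries a waiting-time/destination policy, and
RED discriminators additionally flag the fast path (immediate care first,
classification recorded retrospectively).

Assumptions worth making explicit: all four vitals are measured (missing
vitals are an error, never imputed); pain arrives as a 0–10 number from an
age-appropriate instrument; the fever *report* is a single number, the
highest AxT peak reported for the current illness in the last 24 h; return
counts are supplied, not derived from visit logs; burn severity arrives as a
category (surface-area computation is out of scope).

## Tunable parameters

All clinical numbers live in two JSON files loaded at run time; the code
contains no thresholds.

* `vipe_tables.json` — age strata (day boundaries), score bands per
  (stratum, parameter), fever-correction cut points (37.5 / 38.5 °C, HR
  sub-score gate 2), color legend, and the policy map (waiting times
  0/10/30/90/180 min; destinations resuscitation/observation/waiting room).
* `catalog.json` — one discriminator entry per table cell: code, label,
  category, asserted level, a declarative guard, a mandatory flag and a
  provenance string. Guards are conjunctions of three condition kinds
  (finding present; numeric comparison on a named field; categorical
  equality) with two combinators, `any` (OR of conjunctions) and `none`
  (negation), needed because several printed cells contain "or"
  (the glucose age-split cells) or "without" (edema without hypertension,
  dengue without warning signs).

Defaults reproduce the published tables verbatim. Noteworthy derived
defaults:

* **Age boundaries.** The source states strata in months/years only. Days
  are converted with 1 month = 30.4375 days and 1 year = 365.25 days, giving
  stratum edges at 91, 365, 1826 and 4749 days. The choice is deterministic
  and configurable; where an infant of exactly "2 months plus some days"
  belongs is a convention, not a published fact.
* **Age cut-offs in guards** use the same conversion: "< 3 months" = < 91 d,
  "< 2 years" = < 731 d, "< 3 years" = < 1096 d, "≤ 1 year" = ≤ 365 d.

## Numerical and rule-dialect choices

* **Integer band dialect.** The tables print inclusive integer bands
  ("20–29", "30–60"). Measured values are rounded half away from zero to the
  integer grid, then looked up; this matches the printed grid without
  inventing real-valued cut points.
* **Overlap resolution.** The printed 5–12 y heart-rate row contains an
  overlap ("<51" scoring 4, then "50–60" scoring 2): the value 50 is claimed
  by both. Whether this is a typo for "<50" or "51–60" cannot be known, so
  the loader flags the overlap as a warning and lookups resolve any overlap
  to the *higher* sub-score — the triage safety-first convention.
* **Temperature edges.** Literal reading of the printed bands: 37.5 °C and
  38.5 °C both take −1; the −2 band starts strictly above 38.5 °C.
* **Clamp at zero.** The published range is 0–12 but negative raw sums (for
  example sub-scores 0 + 2 + 0 with correction −2) are never addressed; the
  total is clamped at 0, preserving the stated range.
* **BLUE cells never trigger.** The general table has BLUE-column cells ("no
  pain (0)", "looks well") and so does the complaint table ("minor injury
  without bleeding"). Because the system is upgrade-only and BLUE is the
  floor, a BLUE assertion can never change a classification; these cells are
  catalogued (the census counts them) but evaluation reports them as not
  triggered. This also keeps "nothing wrong" encounters returning an empty
  trigger set, which is the behavior a triage nurse would expect of the
  report.
* **Tachypnea.** The footnote defines tachypnea as "RR score > 0". Encoded
  as the *tachypnea complaint* AND RR sub-score ≥ 1, not the numeric
  condition alone: the complaint table is consulted per reported complaint,
  and a bare numeric guard would silently upgrade every patient with any
  elevated RR to YELLOW, contradicting the upgrade-only round trip (a
  finding-free encounter classifies exactly to its VIPE color).
* **Absent optional measurements.** A guard needing an absent field (blood
  glucose, blood pressure) does not trigger and never raises; because the
  footnotes *mandate* measuring these in specific situations, the evaluator
  additionally returns a "measurement indicated but absent" advisory listing
  the fields — a workflow prompt, deliberately separated from
  classification.
* **Fast path scope.** Only RED-level entries are fast-path triggers; the
  published examples (seizures, impaired consciousness, apnea, cyanosis) are
  all RED, and extending the fast path to ORANGE entries would be an
  invention.
* **Kappa.** The agreement statistic is Fleiss' multi-rater kappa with
  per-category components — the standard choice for a fixed number of raters
  per case and nominal categories. The standard error is the Fleiss
  large-sample formula under the null of chance agreement and the p-value is
  the one-sided upper normal tail (the directional "better than chance"
  question). A category never used by any rater has no defined per-category
  kappa and is reported as `NA`, not 0 — reporting 0 would fabricate
  evidence of chance-level agreement where there is no information at all.
* **Chi-square.** Pearson statistic, expected counts and upper-tail p are
  computed from first principles (only `pchisq` is borrowed); all-zero rows
  and columns are dropped first (the RED row of the validity pre-test table
  is all zero), and visits with missing resource counts are excluded before
  testing — consistent with the printed retained total of 82 of 95 records.
  No continuity correction by default (r×c table). Because several expected
  cells fall below 5, the result carries a warning and an optional
  Monte-Carlo p is offered: tables resampled under fixed margins
  (`r2dtable`) with the add-one estimator (k+1)/(B+1), which cannot return
  0 and is consistent for the exact conditional p.
* **Both percentage bases.** The printed validity table mixes bases: the
  frequency column uses all 95 records, the "Total" column the 82 with known
  resource use. `level_frequencies()` reports both, labeled.

## The synthetic world

The generator (`synth_cohort`, `synth_vitals_for_total`, `synth_vignettes`,
`simulate_raters`) exists so that every statistical claim in the test suite
is computed on data with *known* ground truth.

What it emulates: the urgency-mix and resource-use structure of the validity
pre-test (per-level categorical distributions over the resource bins
0/1/2/≥3) and the design of the reliability pre-test (36 vignette cases,
9 raters, 5 categories, category mix 8/8/31/42/11 % from BLUE to RED).
Intended urgency levels are realized exactly: either the VIPE total is drawn
from the level's own band, or (with probability `discriminator_rate`) from
the band one color below plus a single injected presence-finding asserting
the intended level. Only single-finding presence guards are injected, so the
injected level is exact; mandatory discriminators are held silent (pain 0,
appearance "well", no fever report, no returns, age ≥ 29 days — the newborn
rule would floor every younger infant at YELLOW). Raters report the truth
with probability `fidelity`, otherwise a uniform other category.

What it does **not** emulate: correlated vital-sign physiology (RR, HR, SpO2
are drawn independently within bands), realistic complaint co-occurrence,
seasonal case mix, or rater error that respects the ordinal structure
(a real nurse confuses YELLOW with ORANGE more often than with BLUE; the
simulator's errors are uniform). Consequently a green round-trip test
establishes that the *engine* is faithful to its tables and that the
statistics behave as advertised on data of known structure — it does not
establish clinical validity or reliability of the tool itself, which only
field studies can.

The published reliability figures (overall kappa 0.79; per-category 0.93,
0.82, 0.73, 0.65, 0.93) rest on an unpublished 36 × 9 rating matrix and are
therefore *design targets* for the simulator, not reproducible quantities;
the acceptance suite replaces them with property-based checks (kappa 1 on
perfect agreement, mean kappa within ±0.02 of 0 over 200 null simulations,
exact oracle equivalence on an exhaustive family of small matrices).

## Known limitations

* The discriminator vocabulary is a controlled code list mirroring the
  printed cells; free-text complaint parsing is out of scope, so encoding
  fidelity depends on the person mapping complaints to codes.
* A handful of printed cells are terse ("Behavior change" RED vs.
  "Irritability" ORANGE in the unspecific row) and are encoded literally,
  without interpreting clinical intent.
* Visit-history linkage (computing returns from logs), queue simulation and
  EHR integration are out of scope by design.
* The ±0.1 tolerance used when comparing reproduced percentages to the
  printed validity table exists only because the source truncates rather
  than rounds some prints (16.6 for 1/6, "23" for 9/39); all underlying
  fractions are reproduced exactly.
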