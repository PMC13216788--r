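---
title: "Semi-automated nvHAP surveillance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated nvHAP surveillance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvhap)
```

## The surveillance problem

Non-ventilator hospital-acquired pneumonia (nvHAP) can affect any
hospitalised patient, so surveillance in principle covers the whole
inpatient population — far too many charts for manual review. The
semi-automated design implemented here splits the work: a rule-based
*preselection algorithm* scans routine EHR extracts and reduces the
population to a candidate list, and human reviewers then confirm or refute
pneumonia on that list only. The two quantities that matter are the
algorithm's **sensitivity** against full manual surveillance (missed cases
are gone for good) and the **fraction of records left to review** (the
workload that determines whether a hospital can sustain the surveillance).

## The preselection algorithm

The unit of surveillance is the hospital stay; a patient readmitted twice
contributes two stays. A stay is preselected when it has at least one
*relevant chest radiology procedure*. Relevance is a conjunction over up to
five indicator streams:

1. **Radiology procedure** (always required): a chest X-ray or chest CT
   performed strictly more than 48 h after admission, or at any time during
   the stay for patients readmitted within 10 days (inclusive) of a prior
   discharge. Procedures of other modalities never trigger.
2. **Radiology report**: the event is discarded when its report explicitly
   rules out pneumonia (text rule below).
3. **Leukocytes**: a count `< 4.0` or `>= 12.0` ×10⁹/L within ±48 h of the
   procedure.
4. **Body temperature**: a measurement strictly above 38.0 °C within ±48 h
   of the procedure.
5. **Intubation**: the event is discarded when the patient was continuously
   intubated throughout the full 48 h before the procedure — such events
   belong to ventilator-associated pneumonia (VAP), which is outside nvHAP
   surveillance.

The algorithm is *adaptable*: a hospital that cannot export a stream simply
disables the indicator, which becomes `NA` and never vetoes. Because every
indicator can only remove events, enabling more indicators always yields a
subset of the stays preselected with fewer indicators. Sensitivity of a
reduced algorithm is therefore *greater than or equal to* that of the full
five-indicator algorithm on the same data, at the price of a longer review
list. This antitone property is the package's central invariant and is
property-tested over seeded synthetic hospitals.

The thresholds (fever > 38.0 °C, leukocytes < 4.0 / ≥ 12.0 ×10⁹/L) follow
the ECDC hospital-acquired pneumonia definition. The temporal relationship
between imaging and the lab/temperature signals is not standardised
anywhere we could adopt it from, so it is deliberately *configuration*: a
symmetric ±48 h window around the procedure by default, adjustable per
hospital in `algorithm_config()`. Boundary semantics are fixed and tested:
strictly `> 48 h` for the post-admission rule, inclusive `≤` for signal
windows, `≤ 10` days inclusive for the readmission gap.

We evaluate lab and temperature signals relative to the radiology
timestamp, not relative to a separately derived symptom-onset time: onset
is precisely what the algorithm does not know before manual review, while
the imaging time is always available and is, in practice, close to clinical
suspicion.

## The report text rule

A report sentence *excludes* pneumonia when it contains at least one
negation term ("no") and one infiltrate term ("infiltrate") and no
restricting term ("but", "left") — restricting terms signal that the
negation is qualified or one-sided. Matching is whole-word,
case-insensitive and diacritics-folded; there is no stemming, inflected
forms are enumerated in the term lists. Sentences are split on `.`, `!`,
`?`, `;` and newlines, with no abbreviation handling: a spurious split can
only break a negation–infiltrate pair apart and leave the report
`NOT_EXCLUDING`, which errs toward manual review — the safe direction,
since a false "excluded" silently loses a case while a false "not excluded"
costs only review time. The same fail-safe orientation applies to empty
reports and any other ambiguity.

Term lists are configuration, not code. The bundled German-style and
French-style lists are reconstructions assembled for this package and
should be reviewed against local report language before production use;
`load_termset()` accepts a YAML file or config block with the three lists.

## Case classification (the emulated reference standard)

Validating the algorithm requires a reference standard: full manual
surveillance. On synthetic data the package emulates it deterministically
from structured case features. Pneumonia is confirmed when radiological
signs, at least one systemic sign (fever, leukopenia, leukocytosis), at
least one clinical sign (cough, dyspnea, worsening gas exchange, purulent
sputum) and hospital acquisition (> 48 h after admission or qualifying
readmission) are all present; microbiological strata are out of scope.
Confirmed cases are split by ventilation status in the 48 h before symptom
onset:

* **VAP** — continuously intubated throughout the full window;
* **nvHAP** — not intubated for a single minute within it;
* **iHAP** (indeterminate) — both intubated and extubated within it.

Downstream statistics use nvHAP as an umbrella term including iHAP and
never VAP. Three conventions were genuinely open and are fixed as follows.
The window is half-open, `(onset − 48 h, onset]`: extubation exactly 48 h
before onset counts as never intubated. A patient intubated during part of
the window and *still* intubated at onset falls between the two published
definitions; we classify this cell as iHAP — VAP is defined by the full
window — flag it in the output, and expose the convention as a parameter.
Symptom onset for synthetic ground truth is the timestamp of the episode's
first qualifying radiology event, since no operational definition of onset
exists for chart reviewers that we could mirror. The two-tier review
(second reviewer on uncertain cases) is emulated by a deterministic
escalation rule — worsening gas exchange as the sole clinical sign — purely
to exercise the review data path; it never alters labels.

## Validation statistics

* **Sensitivity** = detected / reference nvHAP cases, with a two-sided 95%
  Clopper–Pearson interval by default. The CI procedure behind published
  surveillance validations is rarely stated; the exact interval is the
  conservative default for small case counts (48 of 48 detected gives a
  lower bound of `0.025^(1/48)` = 92.6%), and Wilson is selectable.
* **Workload fraction** = preselected / population, Wilson interval by
  default (exact selectable). We use all stays under surveillance as the
  denominator; hospitals restricting surveillance to departments simply
  restrict the input population.
* **Number needed to screen** = preselected / detected; undefined when
  nothing was detected.
* **Sample-size planning**: `ceiling(z² p(1−p) / m²)` reference cases to
  demonstrate sensitivity `p` within margin `m` — 73 cases for 95% ± 5% at
  95% confidence. An exact-binomial mode searches for the smallest `n`
  whose Clopper–Pearson interval fits the margin; it is slightly more
  conservative.
* **Enriched validation cohorts**: because nvHAP is rare, cohorts combine
  all stays with a discharge ICD-10 code in a configurable family (dots
  stripped, prefix-matched — a code *family*, e.g. `U69.0x`) with a seeded
  random sample of long stays (≥ 14 days by default).

Performance reports are aggregate-only by construction — they contain
counts, proportions, intervals and a configuration fingerprint, never stay
or patient identifiers — mirroring the discipline that patient-level data
stay inside the hospital.

## The synthetic hospital generator

`generate_hospital()` provides the test bed: five EHR streams plus
per-stay ground truth. What it emulates:

* stays over a six-month admission window with log-normal length of stay
  (median 4 days, `sdlog` 0.8 — a plausible acute-care mix);
* injected pneumonia episodes at 10/1000 stays by default, split 70/5/25
  between nvHAP, iHAP and VAP (VAP roughly one third of hospital-acquired
  pneumonia, iHAP a rare edge category). Each episode emits a chest
  radiology event > 48 h after admission with a non-excluding report, an
  abnormal leukocyte value and a fever measurement within ±12 h of onset
  (well inside the ±48 h defaults), and device episodes consistent with its
  label's 48 h window condition;
* `signal_noise`: the probability that a case's lab and (independently)
  temperature signal is missing from the record — the mechanism by which
  multi-indicator algorithms lose sensitivity on imperfect data;
* background imaging in non-cases (0.35 procedures per stay-week), with
  reports explicitly excluding pneumonia at a configurable rate, routine
  labs and vitals with occasional incidental abnormalities, short-gap
  readmissions, and rare unrelated intubation episodes;
* report text is closed-loop templated: excluding reports are built to
  satisfy the text rule, non-excluding ones — including adversarial
  sentences carrying negation, infiltrate *and* a restricting term — are
  built to fail it, and every render is verified against
  `classify_report()` before use.

Every output table draws from its own RNG stream derived from the scenario
seed, so extending the generator with a new table cannot perturb existing
draws, and a fixed seed reproduces the dataset byte-identically.

What it does **not** emulate: free-text clinical notes (clinical signs are
structured flags, because manual review is emulated rather than parsed),
realistic report prose beyond the templates, seasonal or departmental case
mix, coding error structure, or calibration to any real hospital's
population. Tests passing on this generator therefore demonstrate the
*logic* of the algorithm — boundary semantics, monotonicity, agreement with
naive re-implementations, statistical correctness — not its sensitivity on
real radiology language, which is exactly why validation against a locally
reviewed cohort remains mandatory after implementation.

## Numerical and degenerate-input choices

Timestamps are minute-resolution in a single implicit hospital timezone (no
timezone arithmetic). Leukocyte units are fixed at ×10⁹/L with no
auto-detection — silent unit guessing is a classic surveillance bug. Rows
with malformed timestamps or unresolvable stay references are dropped and
counted in a load log rather than failing the load; an empty stays table
("no population under surveillance") and overlapping stays of one patient
(ambiguous timeline) are hard errors. Abutting device episodes are merged
before any window logic, so splitting an episode into contiguous pieces
never changes a classification. An empty reference (zero nvHAP cases)
makes sensitivity an error, not a number.

## Problem sizes used in the test suite

The bundled validation suite runs the full pipeline at desk scale: the
noise-free sensitivity-by-construction check uses one 5000-stay hospital
across all 16 indicator subsets; monotonicity uses twenty 500-stay
scenarios with 25% signal noise and elevated incidence (30/1000) so that
every scenario carries cases; oracle-equivalence checks run one hundred
200-stay hospitals against naive per-stay re-implementations; the text-rule
round trip covers 1000 rendered reports per language. These sizes give
stable verdicts while keeping the whole suite in the minutes range.

## Known limitations

* The bundled term lists are reconstructions; sensitivity of the report
  rule on real reports depends entirely on locally validated lists.
* The generator's case signals are emitted relative to onset; algorithms
  evaluated with windows narrower than 12 h would miss cases by
  construction of the generator, not by a property of the method.
* Specificity and positive predictive value are not estimated — the
  semi-automated design reviews every preselected stay, so false positives
  cost time rather than accuracy, and the reference standard on real data
  (full manual surveillance) is what validation cohorts approximate.
* The stay, not the patient, is the unit of surveillance; a patient with
  two qualifying stays counts twice in both numerator and denominator.
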