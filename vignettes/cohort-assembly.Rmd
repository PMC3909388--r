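---
title: "Assembling a matched case-control cohort from coded EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling a matched case-control cohort from coded EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cohortflow)
```

## The problem

Hospital informatics platforms (i2b2 and its relatives) let a research team
pull a candidate cohort out of billing data with a boolean query over
ICD-9-CM and CPT code sets, but billing codes are an imperfect proxy for
clinical truth. In the study design this package implements, a team
assembling a pediatric case-control cohort — gastrostomy-tube (G-tube) fed
children with an incident kidney stone as cases, G-tube-fed children without
a stone code as controls — must follow the automated query with manual chart
review: verifying the stone and the G-tube, checking the diagnosis date
against a study period and an age range, applying a tube-feed exposure rule,
and sequentially reviewing randomly ordered matched control candidates until
two eligible controls per case are found. Every candidate ends in exactly
one disposition — inclusion or a single named exclusion reason — and the
dispositions are tabulated into a CONSORT-style attrition table.

`cohortflow` implements that whole workflow as composable, deterministic
pieces, plus a calibrated synthetic-EHR generator so the pipeline can be
exercised, tested and taught without access to patient data.

## The data model

Three layers, all plain delimited text:

* **Coded events** (`patient_id`, `code_system`, `code`, `date`) — the only
  layer the phenotype query engine may see. Code systems are `ICD9-DX`,
  `ICD9-PX` and `CPT`; the study's G-tube definition deliberately mixes
  diagnosis and procedure codes while the stone definition is
  diagnosis-only.
* **Demographics** (`patient_id`, `dob`, `sex`).
* **Clinical truth** — the latent layer a chart reviewer would extract:
  verified stone status and diagnosis date, verified G-tube status and
  placement date, tube-feed exposure as a set of calendar `YYYY-MM` months,
  and a flag for adequate nutrition documentation.

Separating the event layer from the truth layer is what lets the package
model coding inaccuracy: a patient can carry a stone billing code while the
chart shows no verifiable stone.

## Screening rules and their precedence

`assess_case()` applies the clinical criteria in a fixed order and reports
the *first* failing rule: stone unverifiable, G-tube unverifiable, diagnosis
outside the study period (2005-01-01 to 2011-12-31), age at diagnosis
outside 1-21 completed years (inclusive at both ends), stone/G-tube
asynchrony (stone predating placement, or feeds in fewer than 3 of the 12
look-back months), inadequate nutrition data. A record failing several rules
therefore lands in exactly one category, which is what makes the attrition
rows mutually exclusive. The underlying study reports mutually exclusive
counts without stating an order; we use the listing order of its criteria
and expose `precedence` as an argument, since the per-category counts (not
the total excluded) depend on it.

Controls are screened by `assess_control()` against their matched case's
diagnosis date (the *index date*): G-tube verifiable, placed strictly before
the index date, feeds in at least 3 of the 12 months ending at the index
date, adequate data. Controls are never checked against the age range or
study period directly; they inherit their temporal anchoring from the case.

Two calendrical conventions worth stating exactly:

* **Age** is completed years with a birthday-based floor; a February 29
  birthday counts as attained on March 1 in common years.
* **The feed window** is the 12 calendar months ending at, and including,
  the month of the index date; feed exposure is counted in distinct
  calendar months. The source design never defines month granularity;
  calendar months are used because they are auditable from feeding records.

## The synthetic generator

The generator is *label-first and constructive*: it samples each patient's
intended disposition from a configurable probability vector and then builds
a truth record guaranteed to screen as exactly that label, together with
billing events that always satisfy the relevant phenotype query. This
guarantees calibration to the configured proportions and yields an exact
(not statistical) round-trip test: for every generated record, the screening
label equals the intended label, at any seed. A mechanistic alternative —
simulating per-code sensitivity and positive predictive value and letting
dispositions emerge — would be more realistic but cannot be calibrated
exactly; it is deliberately out of scope.

Defaults are the observed study conditions: 177 potential cases with
disposition probabilities 41:28:3:42:35:14:13:1 (included; no stone; no
G-tube; age; period; asynchronous; inadequate data; no eligible control)
over the eight case labels; control candidates eligible with probability
0.165 per review, ineligible reviews split 31:82:293 over no-G-tube /
asynchronous / inadequate-data; matching ratio 2; date-of-birth tolerance
366 days (a leap-year-safe reading of "within one year"); candidate pools
capped at 100 per case.

Where the study reports nothing, the generator makes one fixed, documented
choice rather than exposing a dial: sex is 50/50; diagnosis dates are
uniform over the study period; ages are uniform over 1-21 (out-of-range
records draw uniformly from age 0 and 22-30); event dates are uniform over
a 1998-2013 horizon; feed exposure is a run of 3-12 consecutive months
ending at the index month; ineligible-feed records carry 0-2 such months.
The intended label `NO_CONTROL` is realized as a fully includable case whose
candidate stream the pipeline forces empty — control availability is a
matching-stage outcome, not a chart-review one.

One constructive subtlety: an eligible control needs a G-tube placed and
three feed months strictly before the index date, which is impossible for a
candidate born within a few months of the index date. For candidates
intended `ELIGIBLE` or `INADEQUATE_DATA` the generator therefore tightens
the upper end of the date-of-birth offset (to 160 days before the index
date) when the full ±366-day window would reach past it; the other labels
use the full window. This slightly skews the birth-date distribution of
eligible controls matched to cases diagnosed in infancy, a trade accepted
to keep the per-review eligibility probability exactly the configured
constant.

What the generator does *not* emulate: per-code error rates, longitudinal
visit structure, free-text notes, censoring, or correlation between
disposition and demographics. Passing tests therefore demonstrate that the
pipeline machinery is correct and calibrated, not that it would recover
truth from any particular real hospital's coding behavior.

## Matching and sequential review

`automated_match_pool()` is the deterministic first stage (same sex, birth
dates within tolerance, order-preserving). `sequential_review()` shuffles a
case's pool with the current RNG state and screens candidates one at a time,
stopping at the second eligible control or pool exhaustion; candidates past
the stopping point are never opened. `run_matching()` iterates cases in
sorted-id order and, by default, allocates controls *without replacement* —
the study does not state whether a control could serve two cases, and
one-control-one-case is standard matched-design practice; a `replacement`
flag flips it.

The per-case review-count statistic counts *ineligible* reviews, excluding
the accepted controls, because total excluded reviews over final cases
(406/41 = 9.9) reproduces the study's reported mean exactly under that
convention; `include_accepted = TRUE` gives the other reading. Under iid
per-review eligibility `p` and an unbounded pool, the count is negative
binomial with mean `2(1-p)/p` (about 10.1 at `p = 0.165`), which the test
suite checks by simulation; the finite default pool (cap 100) truncates
that distribution only with negligible probability.

## Attrition reporting

`tabulate_flow()` counts dispositions in the fixed attrition-table order,
with row percentages over the exclusion total and a headline
included-over-identified percentage. The control denominator is the number
of charts actually reviewed, not the full automated pool, matching how such
studies report control yield (80/486 = 16.5%). Percentages are recomputed
from counts on every render — nothing stores a rounded percent — and round
half-up to one decimal everywhere. (The source table prints one entry,
1/136, with two decimals and truncation, "0.73"; we report 0.7 rather than
imitate the inconsistency.) The combined "inaccurate query" share — the
no-stone and no-G-tube rows — is reported per role.

## The pipeline and determinism

`run_pipeline()` chains generate → query → screen → match → report, writing
every intermediate as TSV plus a JSON manifest. Each stage reads only the
previous stage's files and derives its own seed from the run seed, so any
stage can be re-run in isolation and reproduce its outputs byte for byte.
Data files are byte-identical across runs with equal seed and config; the
manifest is the single exception, as it records wall-clock timestamps.

Two sampling modes exist at the pipeline level:

* **Stochastic** (default): dispositions multinomial, control eligibility
  iid Bernoulli. Cohort totals vary around the configured margins.
* **Fixed margins** (`fixed_margins = TRUE`): case labels allocated as
  exact largest-remainder counts, and control streams built from the
  configured exact margins (406 ineligible reviews split 31/82/293,
  distributed near-evenly over the reviewing cases with evenly interleaved
  labels; two pools shorted to a single eligible candidate; the
  no-control case's pool left empty). Review order is then taken as given
  rather than re-shuffled — the stream *is* the realized random order. This
  mode reproduces the full attrition arithmetic (177/136/41 cases at 23.2%,
  486/406/80 controls at 16.5%, and every category row) deterministically,
  which is what makes exact end-to-end regression tests possible. The exact
  control margins are a pipeline-level extension of the documented
  case-side fixed-margins idea; they live in
  `generator_config()$fixed_control_margins`.

```{r, eval = FALSE}
out <- file.path(tempdir(), "demo")
run_pipeline(generator_config(), out, seed = 1, fixed_margins = TRUE)
cat(readLines(file.path(out, "report.txt")), sep = "\n")
```

## Numerical and degenerate-input choices

* Probability vectors must sum to 1 within 1e-9; raw counts are accepted in
  YAML configs and normalized.
* An empty population flows through all five stages and yields all-zero
  tables with undefined (NA) headline percentages.
* Largest-remainder allocation breaks fractional-part ties by position.
* `percent()` adds 1e-9 before flooring to keep binary representation from
  flipping a half-up boundary.
* Problem sizes in the test suite follow the study conditions: round-trip
  screening is checked on 10,000 records over five seeds, oracle
  equivalence on 1,000 random inputs per engine, the review-count law on 41
  cases over 500 replicate cohorts (depth-120 pools stand in for unbounded
  ones; the exhaustion probability is below 1e-7), and multinomial
  calibration at n = 10,000 within three standard errors.

## Known limitations

* Code matching is by exact normalized literal; there is no ICD-9 hierarchy
  or range expansion (the study enumerates its codes, including the four
  536.4x literals, explicitly).
* No date restriction is applied at query time, mirroring the study, which
  applied temporal criteria only at chart review; a date-window filter
  would be a natural refinement.
* The truth layer holds a single stone diagnosis date, so "incident" is
  operationalized as that date lying inside the study period, with
  prior-history patients realized under the asynchronous label.
* Reported per-category exclusion counts depend on the (configurable) rule
  precedence; only the included/excluded split is invariant to it.
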