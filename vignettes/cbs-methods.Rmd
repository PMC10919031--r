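---
title: "Community-based surveillance: thresholds, lifecycle and attribute metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-based surveillance: thresholds, lifecycle and attribute metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbsengine)
```

## The surveillance model

`cbsengine` models a community-based surveillance (CBS) programme as a
flow of typed records:

1. **Reports.** Volunteers registered to villages (with static WGS84
   coordinates representing a random point in the village, not a
   household) submit coded SMS payloads. Every payload is classified
   *signal* (the bare digits of a configured code), *zero report* (a fixed
   token, default `"0"`, confirming "nothing to report" at week's end), or
   *malformed* (anything else). Classification is total and pure: the
   same payload always maps to exactly one status, and malformed is a
   category, not an error. The true platform SMS grammar is richer
   (multi-field payloads, language variants); the dialect here is a
   documented stand-in, flagged `synthetic_standin` in its config.
2. **Events.** Each community case definition (CCD) carries an alert
   threshold. A threshold of one means every signal becomes a pending
   health event at its own time and place. The acute diarrhoeal disease
   CCD is a spatiotemporal cluster rule — five reports within seven days
   and twenty kilometres — described below.
3. **Lifecycle.** A supervisor verifies each pending event (target:
   within 12 h), either keeping it or dismissing it with a reason (not
   matching the CCD, duplicate, sent incorrectly). Kept events are
   escalated as alerts to the health authority; alerts are eventually
   closed with an outcome record (documented / action taken / laboratory
   confirmed), or closed as dismissed by the authorities — a terminal
   status the descriptive tables count as a subset of closed alerts.
   The ledger's transition log is append-only: corrections are new
   entries, never mutations, and replaying the same ordered log onto the
   same initial ledger reproduces the identical final ledger.

## The cluster rule

"5 reports within 7 days in 20 km distance" is operationalised as an
**anchor-greedy rolling window**:

* "7 days" is a rolling 168-hour window anchored at the earliest
  unassigned signal, not calendar days — rolling windows are the standard
  reading for outbreak thresholds and avoid timezone edge cases;
* "20 km" is measured from the anchor signal's location (not a pairwise
  diameter), matching the operational reading "reports within 20 km of an
  index report" and keeping detection linear in the window size;
* distance is the haversine great-circle formula with mean Earth radius
  6371.0088 km; alternative formulas differ by about a metre, immaterial
  against a 20 km threshold;
* the stream is processed online in arrival order, with ties broken by
  (timestamp, volunteer id, report id) so results are deterministic. A
  new signal first tries to join an already-open cluster event whose
  anchor window and radius admit it; otherwise it enters the unassigned
  pool, which is scanned anchor-by-anchor in time order — an event
  triggers at the exact arrival of the threshold-reaching signal, with
  the qualifying signals as members;
* a signal belongs to at most one event of its code (a single outbreak
  should not spawn duplicate alerts), and membership stays open to later
  qualifying signals until the event is verified.

Whether the platform measures the radius from the first report, pairwise,
or from a village centroid is not documented; the anchor-based choice is
the package's documented assumption, and the test suite pins the exact
semantics against an independently coded exhaustive detector (different
data structures, `geosphere` distances) on thousands of random small
streams. All delay comparisons use closed bounds — a delay of exactly
12 h counts as "within 12 h" — the common convention in surveillance
reporting.

CCD definitions carry validity intervals, so a definition can be revised
mid-programme (as happened when a COVID-19 case definition was realigned);
the engine applies the definition active at each signal's timestamp rather
than special-casing revisions.

## Attribute metrics and rounding

Every system attribute is a ratio of ledger counts:

| attribute | numerator / denominator |
|---|---|
| usefulness (escalation) | alerts escalated / events triggered |
| usefulness (response) | alerts closed / alerts escalated |
| simplicity | signals verified / sent; signals kept / verified |
| data quality | correct-format reports / all reports; weekly completeness |
| sensitivity proxies | documented, action-taken, lab-confirmed, authority-dismissed shares |
| timeliness | verified within 12 h and 24 h / events; closed within 48 h / closed alerts |

Percentages are rendered as integers under a single **round-half-up**
rule, computed in integer arithmetic so 92.5 always renders 93. Published
descriptive tables of this kind are not always internally consistent —
some rows read as truncation or as the complement of a rounded
complement — and the report's footnote says so; a single consistent rule
beats mimicking any one table's mixture. The 12 h / 24 h verification
cuts use **all triggered events** as denominator, which is the reading
that makes the within-12 h shares come out as printed. Zero denominators
propagate typed nulls (`NA` percent with the raw counts retained), never
errors; when no alert has a documented outcome at all, every sensitivity
proxy is null and the report is flagged "insufficient documentation" —
mirroring the evidence gap such programmes actually face.

Weekly completeness counts a volunteer as present in an ISO-8601
(Monday-start) week if they sent **any** report that week — signal, zero,
or malformed. A malformed submission still demonstrates an active
volunteer, and the rule keeps the completeness estimator unbiased for the
configured weekly reporting probability. Volunteers enter a week's
denominator only when their active interval overlaps it, weeks with no
active volunteers are excluded, and the period average is the unweighted
mean of weekly fractions.

## The synthetic-programme generator

`sim_config()` defaults describe one region-year at the scale of the
larger 2021 region: 67 villages × 2 volunteers over the 52 ISO weeks of
2021, weekly reporting compliance 0.66, malformed rate 0.02, background
signal rates sized to roughly 550 signals per year with the observed code
composition (respiratory ≈ 57%, ADD ≈ 21%), verification delays a
two-component mixture (mass 0.84 uniform on 0–12 h plus a 12 h +
log-normal tail), supervisor dismissal 0.10, closure mass 0.715 within
48 h, outcome documentation 0.635, action given documentation 0.90,
laboratory confirmation 0.11 of actioned alerts, authority dismissal
0.05. Where the evaluation reports a range across the two regions, the
default is the midpoint; the mixture tails (log-normal, meanlog
`log(10)`/`log(24)` hours) are minimal structure reproducing the printed
delay cuts, since only the within-bound masses are observable.

Background signals are placed uniformly over villages and weeks, so ADD
clustering arises **only** through explicit `outbreak_injection()`s; an
injection draws its reports from volunteers within `spread_km` of the
epicentre and within `spread_h` of its start, so any injection of at
least threshold size with `2·spread_km ≤ 20` and `spread_h ≤ 168` is
detected with probability one by construction. The generator does not
model real geography, nomadic movement, or network outages — these enter
only as aggregate probabilities — so passing tests demonstrate the
engine's contracts, not fidelity to any real region's spatial process.
The weekly series of real programmes also shows seasonal dips (lowest
compliance in the first quarter) that the constant-rate generator does
not emulate.

The generator is seeded and deterministic: identical configuration and
seed give byte-identical serialised ledgers. `parameter_recovery_report()`
re-estimates the configured rates from replicate simulations; its
configured completeness accounts for the background-signal contribution
(`1 − (1 − p)·exp(−λ)` per volunteer-week), exact when no outbreaks are
injected.

## Fixtures from marginal counts

`fixture_from_marginals()` materialises, with no randomness, a complete
ledger whose summary reproduces a region's published marginal counts
exactly: villages on a coordinate grid spaced far beyond the cluster
radius, events on an hourly grid, verification delays of 1 / 18 / 36 h
and closure delays of 24 / 72 h chosen to hit the 12 / 24 / 48 h cuts
exactly, cluster events holding at least five co-located members and
single-report events exactly one. Inconsistent marginal sets (a subset
count exceeding its superset, or signal totals that cannot be partitioned
into event memberships) are rejected with the violated inequality named.
The two packaged specs record the published 2021 marginals for Awdal and
Togdheer; note one internal inconsistency in the source table — the
24-hour verification row prints the escalation count, while the
timeliness text gives 116 (Awdal) and 212 (Togdheer) — the fixtures carry
the timeliness-text counts and the package reports both the 12 h and 24 h
cuts without attempting to reconcile the two.

## Numerical and testing choices

* Timestamps are UTC throughout, serialised ISO-8601 with explicit `Z`;
  CSV interchange is RFC 4180, UTF-8; a write-then-read round trip is the
  identity on every field.
* Event, alert and report ids are deterministic zero-padded sequences in
  trigger/escalation order.
* Property checks run at desk scale, chosen to give tight binomial error
  bands while keeping the default suite fast: the engine-versus-oracle
  equivalence uses streams of 4–12 signals (10,000 in the acceptance
  check), rate-convergence uses a programme of roughly 10,000
  single-report events, parameter recovery uses 5–6 replicates of
  50-village programmes with 3-standard-error tolerances, and the
  conservation/null-propagation invariants run over 100 randomly
  configured small programmes.

## Limitations

The package evaluates programme data; it is not the reporting platform.
It has no SMS gateway, no automated feedback messages, no user accounts,
and no integration with national surveillance systems. Sensitivity is
deliberately reported only through documented-outcome proxies: whether
all true community health events were detected is unobservable from the
ledger, and closure is treated as evidence that *some* response occurred,
never as clinical confirmation.
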