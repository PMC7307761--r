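---
title: "Methods: simulating and settling an emergency care network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and settling an emergency care network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecnsim)
```

## The problem

Emergency departments routinely fail waiting-time standards not because the
whole region lacks capacity but because demand and capacity are mismatched
node by node. An emergency care network (ECN) lets hospitals and points of
care (POCs) pool capacity by transferring low-acuity patients to whichever
node can see them fastest — provided the transfer rules are clinically
safe and the money flows keep every node financially willing to
participate. `ecnsim` implements that design loop: diagnose each node's
waiting-time capability, simulate the network under a transfer policy, and
settle the payments the collaboration generates.

## The network model

A scenario (`network_scenario()`) describes nodes, calendars and money:

* **Nodes.** Each node is a hospital or POC with an ED bed count (absent
  beds = ED disabled; such a node accepts no arrivals and is never a
  destination), an insurer agreement set, semester demand moments, baseline
  and post-improvement waiting-time moments, and per-stage service-time
  distributions with server counts.
* **Calendar.** Time is in minutes, the week starts Monday 00:00, and the
  day is split into three 8-hour slots with half-open boundaries
  P1 = [00:00, 08:00), P2 = [08:00, 16:00), P3 = [16:00, 24:00). Arrivals
  at each enabled node follow 21 weekday-by-slot interarrival pipelines —
  the partition that input analysis of this kind of system typically finds
  necessary, since "time between arrivals" is the one heterogeneous input
  variable.
* **Transfer times.** One square minute matrix per slot, asymmetric by
  design (road networks are directional). Only the afternoon matrix of the
  reference case is published, so the fixture replicates it across slots;
  per-slot overrides are supported. Entries are treated as total
  door-to-door transfer times (whether dispatch overhead is included in
  the source is unstated; we adopt the total-time reading).
* **Money.** An insurer roster with affiliation counts and agreed unit
  utilities `M`, the payment parameters (`gamma`, `theta`, per-arrangement
  floors, destination-to-arrangement map), and the uncovered/special-regime
  population (treated, never transferred).

## Discrete-event engine

`simulate_ecn()` is an event-driven simulator with two event classes
(arrivals, stage completions) plus transfer arrivals.

* **Flow.** arrival -> triage -> (transfer decision) -> admission -> bed
  preparation -> nursing assistance -> physician assessment -> treatment ->
  departure. The waiting-time metric is door-to-physician: minutes from
  arrival to the start of physician assessment. (For reduced single-stage
  stations the start of the only stage plays that role, which is what makes
  M/M/c validation possible.)
* **Queue discipline.** Priority by triage level (1 most urgent), FIFO
  within level. The discipline is a clinical convention of ours — sources
  of this kind rarely state one. For a single-class station the overall
  mean wait is discipline-invariant, so the queueing validation below is
  unaffected.
* **Beds.** A bed is seized when bed preparation starts and released at
  departure. An arrival whose bed request finds all beds occupied is
  counted *blocked* but still queues — we model blocking as a congestion
  signal, not as loss, because no loss rule is published and EDs do not
  turn away admitted patients. The daily blocking series feeds
  `detect_warmup()`.
* **Transfers.** The decision epoch is immediately after triage
  completion. A transferred patient travels for the slot-specific matrix
  time (slot of the decision epoch) and re-enters the destination at its
  post-triage point: triage is not repeated. Whether re-triage happens in
  practice is unknowable from published descriptions; skipping it is the
  conservative reading (triage grades are portable paperwork). Transfer
  chains are forbidden by default (`allow_retransfer = FALSE`): one
  transfer per patient, configurable.
* **Determinism.** All randomness flows through R's session RNG from the
  single `seed` argument; identical seeds give bitwise-identical patient
  logs. `run_replications()` derives per-replication seeds from one
  `base_seed` draw.

### The expected-wait estimator

The transfer inequality needs "the waiting time offered" by each node,
which no published description defines operationally. Two estimators are
provided:

* **Dynamic** (drives the simulator): patients ahead of the arriving
  patient — queued at or above its priority in the stages up to physician
  assessment, plus those currently in pre-physician service — times the
  mean pre-physician service time, divided by the bottleneck server count
  of that segment. It is deliberately simple: a decision-support system
  would compute exactly this from its live queue board.
* **Planning** (static): a per-node table of mean waits, by default the
  post-improvement means carried by the scenario (`planning_waits()`).
  This reproduces desk reasoning — e.g. from POC1 the best candidate is
  H2 at 3.71 + 19 = 22.71 min against POC1's own 126.03 min — and is the
  mode used by `transfer_plan()`.

Ties between candidate destinations break to the lexicographically first
node id, so decisions are reproducible under permutation of the candidate
list.

## Collateral settlement

For a transferred admission the destination receives
`max{floor(arrangement), M (1 + r) / (1 + gamma + theta)}` and the origin
keeps `M` minus that; a node treating its own patient keeps `M` in full.
Two numerical points deserve note:

* **Denominator.** Renderings of this model are ambiguous between
  `1 + gamma * theta` and `1 + gamma + theta`. Back-solving every worked
  per-admission share in the reference case (6.36 = 10.34 x 1.015 / d,
  7.08 = 10.34 x 1.13 / d, 6.25 = 9.97 x 1.035 / d) forces d = 1.65 =
  1 + 0.19 + 0.46, so the sum form is implemented; the product form is
  available via `settlement_rule(..., denominator = "product")` for
  sensitivity analysis only.
* **Rounding.** Arithmetic is exact internally; reports round
  half-away-from-zero to cents (unit shares) and to whole dollars
  (totals), which reproduces the reference coalition ledger cell-for-cell
  in its non-anomalous cells. Two printed cells of that ledger are
  mutually inconsistent with conservation (its origin-side COO cell) or
  with the formula (a 6.13 rate quoted for SV); the package reproduces the
  conservation-consistent values instead.

`estimate_r()` is a Pearson correlation between a destination's per-period
mean wait and the transferred admissions it received, clamped at zero from
below (the compensation term can only raise the destination share), with
weekly aggregation by default in `settle_replication()` — the aggregation
window is not published, and weeks are the natural demand cycle here.

## Capability diagnostics

`capability_metrics()` is one-sided by construction (waiting time has an
upper specification limit only): `Zu = (USL - mean)/sd`, `Cps = Zu/3`,
`P(error)` the upper-tail normal probability, `PPM = 1e6 P(error)`,
efficiency its complement, short-term sigma = `Zu`, long-term sigma =
`Zu - 1.5` (the conventional shift). Printed Cps/PPM pairs in older
reports are occasionally inconsistent with their own printed mean/sd; the
package always applies the standard formulas and treats `Zu` and the sigma
pair as the authoritative cross-checks. `capability_from_series()` adds a
correlation-type normality check (Shapiro-Francia, the Ryan-Joiner family;
at most 5,000 points are tested for long series) and warns below p = 0.05,
because every index above assumes normal waits.

`individuals_chart()` uses the standard X-mR constants: individuals limits
at the mean plus/minus 2.66 times the mean moving range, range-chart upper
limit 3.267 times the mean moving range.

## Input analysis

* `runs_test()`: runs about the median with the normal approximation,
  dropping observations equal to the median; both the raw run count and
  the standardized statistic are reported, since published "k" columns are
  ambiguous between the two.
* `homogeneity_test()`: Kruskal-Wallis with the Homogeneous/Heterogeneous
  label at alpha = 0.05.
* `fit_distribution()`: equal-probability binning with
  `max(5, floor(n/50))` bins capped at 30 and `bins - 1 - p` degrees of
  freedom — the binning rule is ours, no source states one.
* `partition_arrivals()`: assigns arrivals to the 21 cells (half-open slot
  boundaries, so an 08:00:00 arrival is P2), computes within-cell
  interarrival gaps inside contiguous day-slot blocks (never across
  blocks, which would manufacture week-long gaps), and tests across cells
  with Kruskal-Wallis by default; a classical one-way F-test is available
  to mirror ANOVA-based practice. The rank test is the default because
  interarrival gaps are strongly skewed.

## FMEA

`score_risks()` computes RPN = S x F x D and flags RPN > 125 risks:
double-star at severity 8-10, single-star otherwise. Published band
definitions leave severity 7 unassigned (8-10 vs < 7); it maps to
single-star here — it exceeds the RPN threshold, so it is still
prioritized, just not in the highest band.

## Synthetic scenarios and what the tests show

`generate_scenario()` draws structurally valid networks: semester demands
(hospitals 9k-70k, POCs 6k-16k patients), beds (12-40 / 8-15), partial
insurer coverage (each insurer held with probability 0.9), stage service
distributions from {gamma, lognormal, triangular, uniform} by moment
matching around realistic stage means (triage 4, admission 3, bed
preparation 5, nursing 7, physician 10, treatment 40 min), staffing sized
to roughly 80% utilization, and asymmetric 4-35 min transfer matrices.
The built-in reference case uses the same synthetic service-time defaults,
because its fitted distributions are not published; everything printed
about the case (transfer times, beds, demand and wait moments, insurer
roster and utilities, payment parameters) is encoded verbatim. One roster
count is garbled in the source; it is stored as 247,680, back-computed
from the printed roster total 1,229,996.

What the generator does *not* emulate: seasonal and holiday effects,
within-slot nonstationarity (interarrival draws use the pipeline of the
current weekday/slot at each arrival epoch, a standard piecewise
approximation), correlated service stages, staff rosters, and ambulance
availability. Passing tests therefore show the machinery is correct under
the stated model, not that any real ED follows that model.

Problem sizes used by the test suite are chosen to keep Monte-Carlo error
well inside the assertions: the queueing validation runs 30 independent
120-day replications with a 33-day warm-up (the same warm-up fraction, about
27% of the run, that full-scale studies of this system class use) and checks
the simulated M/M/1 and M/M/2 mean queue waits against the Erlang-C closed
form within the replication t-interval; property suites use 300-1,000
randomized cases and 2,000 null replicates for the runs-test
type-I-error band.

## Known limitations

* Waits of patients still unserved at the horizon are excluded from the
  patient-average, a censoring that biases short-run estimates slightly
  low; use run lengths much longer than the congestion relaxation time (the
  queueing tests above use 120 days).
* The dynamic expected-wait estimator ignores service-time variance and
  downstream blocking; it is a policy input, not an unbiased predictor.
* Projected full-network waiting times for the reference case are not
  reproducible — the fitted input distributions behind them are
  unpublished — so the simulator's claims there are validated structurally
  (queueing closed forms, conservation, determinism) rather than
  numerically.
* Payments ignore transfer transport costs and taxation; alternative
  cooperative allocations (e.g. Shapley values) are out of scope.
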