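---
title: "The wardflow patient-flow model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wardflow patient-flow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardflow)
```

`wardflow` simulates a hospital as a network of queued, capacity- and
resource-constrained wards traversed by stochastically generated patients.
This vignette documents the model, its assumptions, the parameters that
matter, and the numerical and design choices behind the implementation.

## The model

Time is a sequence of discrete steps; one step corresponds to one hour by
default, which makes the default waiting-time target of 4 steps the
familiar 4-hour A&E standard. Each step executes six sub-phases in a fixed
order:

1. **Arrivals** — a uniform draw on `[arrivals_min, arrivals_max]` new
   patients joins the entry ward's queue. The entry queue is unbounded:
   arriving patients wait "outside" the hospital and occupy no bed.
2. **Treatment** — each ward divides its per-step resource pool among its
   admitted, non-boarding occupants under its resource policy. Each such
   occupant's remaining need falls by its allocation and its remaining
   length of stay falls by one step (both floored at zero). Unused
   resources do not carry over.
3. **Completion** — occupants with no remaining need *and* no remaining
   stay either queue for the next ward on their required pathway (staying
   in their current bed until admitted — "bed blocking") or, if the
   pathway is exhausted, are discharged immediately, freeing the bed.
4. **Queue admissions** — wards admit from their queues into free beds in
   the order given by their queue policy. The sweep over wards repeats
   until a full pass admits nobody, so a bed vacated by a transfer is
   refilled in the same step no matter where the two wards sit in the
   configuration order.
5. **Overflow** — a ward at capacity whose queue is non-empty diverts its
   completed-but-blocked occupants, longest-waiting first, to
   overflow-enabled wards with free beds; each freed bed is immediately
   offered to the ward's queue. Boarded patients keep their place (and
   original entry step) in the queue of the ward they actually need.
6. **Snapshot** — per-ward occupancy and queue lengths are recorded.

A run stops at `max_steps`, or earlier once `max_patients` have arrived
and the hospital has emptied; arrivals cease as soon as the patient bound
is reached so in-flight patients can drain.

### Patients

A patient is a required ward pathway plus per-ward requirements. The
pathway is a random walk on the ward-transition digraph starting at the
entry ward and ending when the absorbing `DISCHARGE` node is drawn; the
walk is truncated at `max_pathway_length` (default 20) wards, which
guarantees termination on cyclic graphs — a truncated patient is simply
discharged after the last generated ward. Per ward, length of stay is
`max(1, Poisson(los_lambda))` — the clamp ensures every visit occupies a
bed for at least one step, without which occupancy accounting would admit
zero-duration visits — and resource need is `Poisson(need_lambda)`. The
two draws are independent; nothing in the model couples acuity to
duration, which is a simplification worth remembering when reading
results. Treatment requires *both* requirements to be exhausted (need and
time jointly), and a completed-but-blocked patient consumes no further
resources (its need is already zero) while it waits.

### Policies

Queue policies order `(patient, queue_entry_step, need_at_destination)`
entries: `chronological` by entry step, `high_need_first` /
`low_need_first` by the patient's need at the ward being queued for. The
"need" a ward observes is the patient's total requirement at that ward,
not the remaining whole-pathway need — it is the quantity an admitting
ward could actually assess. All orders break ties by
`(queue_entry_step, patient id)`, making every run deterministic given the
seed. Resource policies divide the pool: `even` uses iterative
water-filling — split the remaining pool equally among patients with
unmet need, cap at need, redistribute the surplus — so no resource is
wasted while any need is unmet; the greedy policies serve patients to
their full need in need order. Allocations are real-valued: integer
rationing would introduce order-dependent rounding artefacts.

Custom policies plug in by name through `register_policy()`; configuration
files may then reference them like the presets.

### Boarding

Diversion exists to free a bed, not to treat: boarded patients receive no
allocation and make no length-of-stay progress in the overflow ward, and
they must return to their required pathway before discharge. Only
non-diverted blocked occupants are eligible for diversion — re-diverting a
boarder would churn beds without freeing net capacity. The destination is
the first overflow-enabled ward in configuration order with a free bed,
excluding the ward the patient actually needs (if that ward has a free
bed, the patient belongs there via its queue, not via boarding).

## The default hospital

The shipped configuration is an emergency department plus seven specialist
wards and exactly 220 beds:

```{r}
default_config()$wards[, c("id", "capacity", "resources", "los_lambda")]
```

Capacities, transition probabilities, Poisson means and arrival bounds are
calibrated inventions — the kind of mid-size acute hospital a teaching
example needs — chosen by steady-state arithmetic rather than fitted to
data. Arrivals are uniform on 0–4 per step (mean 2/hour ≈ 1440/month, so a
one-month run admits roughly 1400 patients). The ED turns patients around
in about 2 hours; specialist stays range from 1 to 4 days
(`los_lambda` 24–96). With the routing matrix in
`default_config()$graph`, each ward's implied bed demand — arrival rate
into the ward times mean stay — sits below its capacity, topping out in
geriatrics (demand ≈ 12.4 of 15 beds, ~85%), the deliberate
near-bottleneck; so the default hospital runs busy but not saturated. `need_lambda` equals
`los_lambda` per ward (one resource unit per expected hour) and ward
resource pools exceed expected per-step demand, so treatment, not
resourcing, paces the default run; starving a ward of resources is exactly
the kind of management experiment the simulator is for. The surgical wards
(`surgery`, `orthopaedics`) accept overflow boarding, mirroring the common
practice of using surgical beds to ease medical overcrowding.

## Analyses

- **Waiting times** — arrival to first exit from the entry ward
  (transfer, discharge, or diversion out of it), matching
  arrival-to-departure 4-hour semantics rather than time-to-admission.
  Patients still in the ED or its queue at run end are censored: they are
  excluded from the percentage and reported as a count, because counting
  truncated waits would bias the target metric optimistically.
- **Occupancy** — per-ward occupants and utilisation per step, taken at
  step end.
- **Flow network** — one directed edge increment per recorded bed
  movement: entry admissions (`EXTERNAL → ED`), transfers, diversions,
  boarding returns, and discharges (`ward → DISCHARGE`). Edge totals
  reconcile exactly with the event log.
- **Network statistics** — weighted and unweighted degrees; normalised
  directed betweenness and harmonic closeness on the unweighted
  edge-presence graph (whether one patient or a thousand made a movement
  does not change which routes exist). Betweenness of a node is the mean,
  over ordered pairs of other nodes that are connected by at least one
  directed path, of the fraction of shortest paths through it — a pure
  relay on a directed line scores 1, and nodes in sparse, partly
  disconnected realised-flow graphs are compared over the paths that
  actually exist. Closeness uses the harmonic form (mean of inverse
  distances, unreachable nodes contributing zero) because realised flow
  graphs are rarely strongly connected and the classical definition
  degenerates there. Both statistics are verified in the test suite
  against a brute-force enumeration of all simple directed paths on
  random graphs of up to six nodes.
- **Journeys** — the required ward sequence a discharged patient actually
  entered; boarding wards are excluded (the patient was parked, not
  treated). Durations are discharge minus arrival step; medians of
  even-sized groups average the two central values. Censored patients are
  excluded and counted separately.
- **Operating cost** — `steps_run × Σ_wards (resources ×
  resource_unit_cost + capacity × bed_unit_cost)`: beds and resources are
  paid for whether used or not, so over-provisioning shows up as cost
  rather than being free slack. Default unit costs are 1 (resource) and
  2 (bed) per step; they are relative weights, not currency.

## Numerical choices

- Need counters are compared to zero with a `1e-9` tolerance; water-filling
  terminates via a `1e-12` floor on progress. Transition rows must sum to
  1 within `1e-9`.
- Ward sweeps (admissions, overflow) follow configuration-file order;
  all within-queue ties break by `(queue_entry_step, patient id)`. These
  rules exist purely to make runs reproducible: identical config and seed
  give byte-identical event logs.
- All randomness flows from one seeded generator owned by the run, in a
  fixed draw order (arrival count, then per patient: pathway, stays,
  needs); generation helpers never seed themselves. The caller's RNG
  state is saved and restored.
- Self-loops in the transition graph are rejected at validation: a
  "transfer" from a ward to itself has no physical meaning in the model
  and would corrupt movement-based analyses.
- A zero-capacity ward is legal (it models a closed ward: patients can
  queue for it but never enter).

## What the tests do and do not show

The test suite exercises the simulator on hand-traceable deterministic
hospitals (constant stays, forced routing), on randomised small hospitals
(2–4 wards, 100–200 steps) for conservation and capacity invariants, and
on the default hospital at full scale (720 steps, ~1450 patients, 20
seeds for the throughput check). Distributional components are checked by
parameter recovery — Poisson means within three standard errors at
n = 10,000, first-transition frequencies by chi-square goodness of fit —
and the network statistics against an independent brute-force oracle on
200 random graphs.

Passing these tests shows the implementation faithfully executes *this*
model. It does not show the model reproduces any real hospital: arrivals
have no diurnal or seasonal pattern, patients have no covariates (age,
acuity class, elective vs emergency), stays are Poisson rather than
heavy-tailed, resources are a single fungible unit, and staffing,
rostering and out-of-hospital delays are out of scope. The simulator is a
teaching and what-if instrument, not a forecasting tool.
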