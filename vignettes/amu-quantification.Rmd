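---
title: "Dose-based quantification of antimicrobial usage in dairy herds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-based quantification of antimicrobial usage in dairy herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovamu)
library(dplyr)
```

## The problem

Farm-level surveillance of antimicrobial usage (AMU) in livestock asks a
deceptively simple question: how much antibiotic was actually given to the
animals, and was it given at a sensible dose? Sales data cannot answer it —
they say nothing about which animals were treated, for what, for how long,
or by whom. The design modelled by this package answers it directly, with
two redundant data streams collected on dairy farms over a year:

1. **Treatment history**: monthly interviews recording, per treatment
   episode, the product, the quantity used, the number and weight of the
   treated adult bovines, the duration, route, indication, and the person
   who administered the drugs.
2. **The bin method**: a dedicated receptacle on each farm into which empty
   drug containers are deposited, emptied monthly. Where a container was
   only partially used, the treatment prescription is collected instead, so
   the true consumed amount is still known.

The modelled population is 38 dairy herds — 20 household herds (5–20 adult
bovines, family labour) and 18 commercial farms (more than 20 animals) —
holding 1,010 adult cattle and buffaloes, observed for 365 days. Heifers
and calves are excluded by schema: they contribute a minor, rapidly
churning share of usage.

## Dose-based metrics

Masses alone mislead: 1 g of ceftiofur represents many more treatment-days
than 1 g of oxytetracycline. Dose-based metrics standardize mass into
counts of daily doses. With `DDDkg` the recommended dose of a substance in
mg per kg bodyweight per day, `w` the recorded weight at treatment (kg),
`n` animals treated, and `d` treatment days:

* **ADD** (animal daily dose, g/day) `= DDDkg × w / 1000` — the standard
  daily dose for one animal. Intramammary products are dosed per syringe,
  not per kg, so there `ADD = mg-per-unit × units-per-administration ×
  administrations-per-day` (mg/day).
* **nADD** `= mass(g) / ADD` — how many standard daily doses the
  administered mass contains. Herd-level nADD sums event-level values.
* **UDD** (used daily dose, mg/kg/day) `= mass(mg) / (n × w × d)` — the
  dose actually given.
* **UADD** `= UDD × w` (mg/day) and **nUADD** `= mass(mg) / UADD` — the
  used-dose analogues of ADD and nADD. Algebraically `nUADD = n × d`
  for an event computed end-to-end; this identity is property-tested and
  is a strong internal consistency check of any implementation.
* **ADUR** (antimicrobial drug use rate)
  `= mass(g) × 1000 / (ADD × periodDays × animalsAtRisk)` — nADD per 1000
  animal-days, comparable across herds and periods.
* **UDD/DDDkg ratio** — dosing adequacy. Below 0.8 is under-dosing, above
  1.2 over-dosing, the closed band [0.8, 1.2] is correct dosing. The edges
  are classified as correct; the band is configurable
  (`metric_config(band = ...)`).

Catalogue resolution precedes all of this. A commercial product maps to
its active components; fixed combinations are interpreted as a single
active substance: a beta-lactam with a beta-lactamase inhibitor
(amoxicillin–clavulanate and kin) resolves to the beta-lactam, and
trimethoprim–sulphonamide combinations resolve to the minor substance,
trimethoprim. Co-formulated partner masses are retained for
mass-conservation audit but excluded from dose metrics.
IU-denominated penicillin concentrations convert at 1 mg = 1,598 IU by
default (configurable, `iu_per_mg`).

WHO critical-importance categorization goes through the antimicrobial
class: quinolones and 3rd-generation cephalosporins map to the
highest-priority critically important antimicrobials (HPCIA),
aminopenicillins and aminoglycosides to high-priority CIA, other classes
to non-CIA categories. This default map is the one effective in the
modelled surveillance data; notably it places penicillins outside the CIA
group. The map is a plain CSV and can be replaced wholesale to follow any
edition of the WHO list.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `band` | [0.8, 1.2] | ratio | dosing-adequacy band, edges inclusive |
| `iu_per_mg` | 1598 | IU/mg | benzylpenicillin unit conversion |
| `fallbackWeightsKg` | 400 / 500 | kg | species median weights when none recorded |
| reconciliation `tolerance` | 0.05 | relative | mass agreement required to match the two streams |
| `adurDenominator` | `"herd"` | — | herd animal-days vs pooled study denominator |

The DDD registry shipped by default is back-calculated from the reference
dataset's median used daily doses divided by the dosing ratios, tagged
`BACKCALC`; it assumes the published ratio is the ratio of medians. An
ESVAC- or label-sourced registry drops in via `ddd.csv` without code
changes, and per-species records take precedence over `BOVINE_ANY` ones.

## Reconciling the two streams

Both streams are reduced, per herd × month × product, to the implied mass
of the dose-determining substance: `empties × unitSize × concentration`
(minus any leftover recorded in the partial-use note) against
`Σ quantity × concentration`. Groups agreeing within the tolerance are
matched; history without bin corroboration and bin-only evidence
(candidate unrecorded or unauthorized use) are reported, not resolved —
the design gives no rule for adjudicating disagreement, so the
`ReconciliationReport` exposes discrepancies as data. Matching is monthly,
mirroring the collection protocol.

## The synthetic generator

`generate_population()` and `generate_treatments()` emulate the modelled
surveillance conditions so the full pipeline is exercisable without any external data:

* **Herds**: 20 household (sizes uniform on 5–20) and 18 commercial
  (21–63, centring total animals near 1,010); species drawn with cattle
  probability 519/1010.
* **Weights**: scaled Beta on the stated [min, max] per species, shapes
  constrained ≥ 1 (unimodal) and fitted by least squares to the stated
  median and mean with the median weighted higher. The four summaries
  over-determine a two-parameter Beta — the stated cattle combination
  (median 400 below the mean 421, which itself lies above the interval
  midpoint) is infeasible exactly — so the fit honours the median (within
  about 1%) at the cost of a mean roughly 4% low. Tests assert the
  empirical median within ±5% at n ≥ 500.
* **Cases**: Poisson per herd with rate 0.15 cases per animal-year,
  calibrated so the expected study total is ≈ 208 cases; commercial herds
  get a 1.5× usage-rate multiplier so the household-vs-commercial contrast
  is recoverable (the design states significance, not effect size).
  Indication mix (mastitis .5048, fever .2067, reproductive .1731,
  diarrhea .0432, misc .0722) and administrator mix (.3421/.2632/.2368/.1579)
  follow the observed frequencies; each case emits `1 + Poisson(265/208 − 1)`
  product administrations with substance chosen by indication-specific
  weights.
* **Dosing behaviour**: administered mass targets
  `DDDkg × weight × days × animals × multiplier(substance)`, the default
  multipliers being the observed per-substance dose ratios, with
  median-preserving lognormal noise (sdlog 0.1, roughly the precision of
  dosing by eye and syringe). Median-preservation is what makes the dose
  ratio recoverable as a median without bias. Durations are uniform on
  2–5 days (the design is silent; short parenteral courses are typical).
* **Bin stream**: syringes draw continuous volumes; empties per
  herd-month-product are `ceiling(volume / unitSize)` with the unused
  remainder of the last container recorded in a machine-readable
  partial-use note (`leftover_mL=x`), standing in for the collected
  prescription. Each group reaches the bin with probability
  `binCompliance`. At full compliance reconciliation matches everything
  exactly; at compliance 0.8 the bin-stream mass recovers ≈ 80% of ground
  truth.

What the generator does *not* emulate: disease transmission dynamics,
seasonal case clustering, per-farm prescriber habits, multi-product
treatment protocols per case beyond independent draws, or heifer/calf
usage. Passing parameter-recovery tests therefore shows the pipeline's
arithmetic and plumbing are sound under the stated structure — not that
the generator is a faithful epidemiological model of any real region.

## The reference dataset

`reference_dataset()` is a deterministic 265-event dataset whose pipeline
outputs reproduce the published summary surfaces of the modelled study
exactly: the product-frequency table (all indication columns), the overall
herd-usage counts, and per-substance summed nADD and nUADD. It exploits an
internal consistency of those surfaces: per substance, summed nADD divided
by summed nUADD equals the published UDD/DDDkg ratio when all events share
one weight. Fixture events therefore use a single 400 kg animal and
fractional durations `nUADD/k` per event, so per-event computed metrics sum
exactly to the published totals — they carry tabulated metric totals and
are deliberately not raw-record realistic (the stochastic generator covers
that). Two published surfaces are *not* reproduced, because they cannot
be: the per-condition herd-usage columns are jointly inconsistent with the
frequency table at condition level, and condition-level nADD shares depend
on unpublished per-event amounts. Published per-herd ADUR magnitudes are
likewise out of reach (their denominator is not derivable from the
published totals); the ADUR formula itself is property-tested and both
herd-level and pooled denominators are exposed.

## Numerical choices

* Percentages are rounded half away from zero to 2 decimals in reporting
  tables only; all metric arithmetic is full precision and rounding is
  deferred to the reporting layer.
* `run_quantify()` aggregates from the serialized `metrics.csv` it has
  just written, so `run_report()` on that file reproduces its tables
  byte-for-byte.
* Degenerate inputs: zero administered mass yields zero metrics; a zero
  grand total makes a share table an error (there is nothing to
  normalize); an identical-samples herd-type comparison reports a zero
  statistic rather than NaN; empty event files produce empty, well-formed
  reports.
* Determinism: all randomness flows through a single integer seed per
  generator call; no time-based entropy.

## Known limitations

* The default DDD registry is back-calculated, not authority-sourced; it
  is intended as a working default and should be replaced with ESVAC or
  label values for regulatory use.
* Events carry no species column; DDD lookup for mixed herds uses the
  configured default species and the species-agnostic registry records,
  and the weight fallback is a single configured median per species.
* The reconciliation tolerance (5%) is a pragmatic default; the modelled
  design does not state how its two streams were merged.
* Problem sizes used in the test-suite simulations (10–20 generator
  replicates of a 38-herd year) were chosen to estimate medians and
  recovery fractions to well within the asserted tolerances.
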