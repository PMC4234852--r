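---
title: "The nucspread model: mechanisms, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The nucspread model: mechanisms, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucspread)
```

## The model

`nucspread` simulates the spreading of covalent histone modifications along
the body of a single gene. The gene is a linear array of `n` nucleosomes
(default 50, i.e. roughly 10 kb at ~200 bp per nucleosome). Each nucleosome
is reduced to two coordinates:

* a **modification state**: acetylated (`A`), unmodified (`U`) or
  methylated (`M`) — stand-ins for active, neutral and silenced chromatin;
* an **occupancy**: empty, or bound by one methyltransferase (`Mt`) or one
  acetyltransferase (`At`). At most one enzyme fits on a nucleosome.

The dynamics form a continuous-time Markov chain whose reaction channels
`enumerate_reactions()` lists explicitly for any state:

| channel | condition | rate | default (s⁻¹) |
|---|---|---|---|
| initiate | initiation site unoccupied | `k_on` | 2.4 (single) / 0.01 (dual) |
| unbind | enzyme bound | `k_off` | 0.1 |
| catalyze_site | bound enzyme on `U` | `k_transferase` | 1000 |
| catalyze_neighbor | bound enzyme, flanking `U` (recruitment/combined) | `k_neighbor` | 0.2 per side |
| slide | empty adjacent nucleosome (diffusion/combined) | `k_slide / 2` per direction | `k_slide` = 0.6 |
| recruit | empty nucleosome carrying the enzyme's own mark (recruitment/combined) | `k_recruitment` per nucleosome | 0.24–4.8 |
| background_acetylate | `U`, single-enzyme models only | `k_background_acetylation` | 2.4 |
| demodify | `A` or `M` | `k_demodification` | 2.4 |
| connect | connectivity-site pair, ≥ 1 enzyme bound | `k_interaction` per pair | 0.01–1 |

Assumptions worth spelling out:

* Enzymes only modify `U` nucleosomes, always writing their own mark;
  demodification (and, in single-enzyme models, background acetylation) is
  ubiquitous and ignores occupancy — a bound enzyme does **not** shield its
  nucleosome from mark turnover. The enzyme may therefore sit on a
  nucleosome of any modification state.
* Array ends are reflective: a border enzyme behaves as if its outer
  neighbour were permanently occupied. Enzymes never pass each other by
  sliding; with connectivity they can exchange across contact sites, which
  is the only way the left-to-right order of enzyme identities can change.
* Initiation is blocked while the site is occupied — in dual-enzyme models
  an antagonistic enzyme parked on the site suppresses influx.
* Recruitment is a per-nucleosome rate: every empty nucleosome carrying the
  matching mark contributes `k_recruitment`. This is what makes the
  **recruitment efficiency** `RE = k_recruitment / k_demodification` (mark
  lifetime over mean recruitment waiting time,
  `recruitment_efficiency()`) the natural control parameter: at `RE < 1` a
  mark usually dies before attracting an enzyme, at `RE > 1` marks
  propagate enzymes.
* Connectivity pairs where both sites are empty are not scheduled: firing
  them would change nothing, and omitting the no-op events leaves the law
  of the visible process unchanged.

## Where the rate constants come from

The `parameters` functions regenerate the defaults from physical constants
(`derive_rate_table()`):

* `k_on` — the Smoluchowski diffusion-limited association rate scaled by
  the nuclear enzyme concentration,
  $4\pi (D_E + D_S)(r_E + r_S)\, n_E / V_{nucleus}$. With an enzyme
  diffusion coefficient of ≈ 3.8 µm² s⁻¹ (inside the 0.5–5 range typical of
  nuclear proteins), 2.5 nm radii for enzyme and site, 5,000 enzyme copies
  and a 500 µm³ nuclear volume this gives 2.4 s⁻¹. The same value serves as
  the demodification and background-acetylation rate. Note the volume must
  be a *human-nucleus* 500 µm³ (0.5 pL); a 500 pL volume would be off by
  10³ and could not reproduce 2.4 s⁻¹ with any plausible diffusion
  coefficient.
* `k_off` — the reciprocal of a 10 s mean chromatin residence time, the
  fast-fraction scale measured for HP1-type readers by FRAP.
* `k_slide` — a 1D sliding coefficient of 2 × 10⁻⁴ µm² s⁻¹ (the low end of
  single-molecule measurements on chromatinized templates) mapped onto the
  25 nm nucleosome spacing: `slide_rate(D, d) = 2 D / d²` ≈ 0.64, the
  working value 0.6 s⁻¹.

**Convention: `k_slide` is the total hop rate.** A lattice walk that hops
at rate λ in each direction has diffusion coefficient $D = \lambda d^2$;
matching the measured $D = 2\times10^{-4}$ µm² s⁻¹ at $d = 25$ nm requires
λ ≈ 0.32 s⁻¹ per direction, i.e. a **total** rate $2D/d^2 ≈ 0.64$. The
simulator therefore schedules two sliding channels at `k_slide / 2` each
("equal chance to move left or right"). Interpreting 0.6 as a
*per-direction* rate would double the effective sliding diffusivity
relative to the measured coefficient. This choice is consequential: the
seeding-bistability fractions and the high-state methylation level computed
by `scripts/acceptance.R` sit several points lower (and closer to the
derivation-consistent expectations) than under the doubled-diffusivity
reading, while pattern establishment is correspondingly slower.

Two documented parameter forks: dual-enzyme models default to
`k_on = 0.01 s⁻¹` (the low-influx regime in which one mark can take over
the array); the elevated 0.1 s⁻¹ variant remains reachable through
`spread_preset(..., k_on = 0.1)` or a config file.

## Simulation engine

`simulate_spread()` runs the **next-reaction method**: every channel keeps
an absolute tentative firing time in an indexed binary min-heap; after an
event only the channels reading the touched positions (the event's
positions, their neighbours, and any connectivity partners) are
re-evaluated, reusing scaled waiting times in the Gibson–Bruck manner. The
classical **direct method** (full propensity recomputation, linear
selection) is retained as an independently coded cross-validation route.
Both are statistically exact; `validate = TRUE` re-derives every propensity
from scratch after each event and aborts on any bookkeeping disagreement.

Numerical conventions:

* Randomness comes from R's RNG, so `(model, init, seed, method)` fixes the
  trajectory bit-for-bit. Ensemble replicates draw one sub-seed each from
  the master seed; any replicate can be re-run alone.
* Ties between tentative firing times (measure-zero, but possible in
  floating point) resolve to the smallest channel index.
* If the total propensity hits zero the state is absorbing and is held to
  the horizon.
* Trajectories record the full event log (`tidy()` returns it; TSV
  serialization via `write_event_log()`); `simulate_ensemble()` instead
  streams per-second time-weighted counts, the positional profile and the
  count distribution inside the engine, retaining no event logs — the
  event-log estimators and the streamed accumulators agree to floating
  point, which the test suite asserts.

## Estimators

All probabilities are **time-weighted**: each inter-event interval
contributes its duration, so estimates are exact functionals of the
trajectory, not snapshot averages.

* `positional_profile()` — per-position probabilities of each mark and each
  enzyme, computed over the final 60 % of each run (configurable
  `steady_fraction`) and averaged across replicates; the three mark
  probabilities sum to one per position.
* `count_distribution()` — time-weighted mass over the total count
  (0…`n`) of a species in the same window.
* `binned_dynamics()` — per 1-s bin, the minimum, quartiles, median and
  maximum across replicates of the bin's time-weighted count. Quartiles use
  linear interpolation between order statistics (`quantile()` type 7), so
  summaries are reproducible bit-for-bit given seeds.
* `establishment_time()` — the first bin at which the median trace reaches
  90 % of its plateau, the plateau being the mean of the median over the
  final 25 % of the horizon. Establishment experiments use the standard
  400-s, 100-replicate protocol; for slowly saturating mechanisms
  (strong recruitment) the 400-s plateau is still rising, so this is a
  protocol-relative, not asymptotic, time.
* `seeding_experiment()` — replicates start from `k` equidistant
  methylated, enzyme-bound seeds (positions
  `floor(n(2i−1)/(2k) + 0.5)`, a symmetric half-up rounding) on an
  otherwise unmodified array. A replicate counts as "high" when its
  time-averaged total methylation over the final 10 % of the run exceeds
  `n/2`; the two end states sit near 0 and ≈ 0.8 n, so any mid-gap
  threshold gives the same classification. Initiation influx is withheld
  by default: the experiment asks whether the seeds alone can ignite the
  self-sustaining state, and with the single-enzyme influx of 2.4 s⁻¹
  active every replicate converts within about a minute regardless of the
  seed count, erasing the phenomenon under study (`influx = TRUE` restores
  it). Fractions come with Clopper–Pearson 95 % intervals.
* `relaxation_experiment()` — starts fully methylated and fully occupied,
  disables initiation, and follows the decay of total methylation.
* `boundary_statistic()` — for dual-enzyme runs, the per-replicate time
  average of (total M − total A) in 10-s windows; its replicate
  distribution locates the modification boundary and detects takeover and
  switching events.

## Validation strategy

Three independent routes guard the implementation:

1. the R-level channel enumerator is checked clause-by-clause against a
   deliberately naive oracle on thousands of random states across all
   mechanism/enzyme combinations;
2. for short arrays the full reachable state space is enumerated with
   `reachable_states()`, the CTMC generator assembled with
   `generator_matrix()`, and the exact stationary law solved by
   `exact_stationary()`; long simulations must match it in total-variation
   distance (both SSA variants, < 0.02 in the tests);
3. event logs replay through the R-level `apply_reaction()` with
   precondition checking, confirming that every event the engine fired was
   enabled and that occupancy exclusivity and enzyme ordering hold along
   the run.

## What the simulations do and do not emulate

The generator reproduces the study conditions: 50-nucleosome arrays,
Table-style default rates, 400-s single-enzyme protocols (1-s bins,
final-60 % steady-state windows), 400-replicate seeding ensembles, 500-s
dual-enzyme runs. Passing tests therefore show that the implementation
realizes *this idealized model*, not that the model captures any particular
locus: real chromatin has nucleosome turnover and eviction, multivalent
marks on one nucleosome, explicitly regulated erasers, protein-complex
assembly steps, and 3D polymer structure — all outside scope. Timescales
here are upper bounds on spreading speed, since every binding intermediate
is collapsed into single first-order steps.

## Known limitations

* State-space tools (`exact_stationary()`) are dense-matrix and practical
  only for `n ≤ 4`; the engine's per-state time accounting is capped at
  `n ≤ 12`.
* The seeding classifier assumes bimodal end states; exotic parameter sets
  with a mid-gap stationary mode would need a different classifier.
* `simulate_ensemble()` fixes the steady-state window at simulation time;
  re-analysing with another window requires event-log recording.
* Establishment times are plateau-relative (see above) and depend on the
  chosen horizon for mechanisms that have not saturated within it.
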