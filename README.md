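# nucspread

Exact stochastic simulation of histone-modification spreading along a
nucleosome array.

Chromatin regions the size of a single gene (~10 kb, modeled as an array of
50 nucleosomes) carry covalent histone marks — here acetylation (A),
methylation (M) or neither (U) — written by transferase enzymes and erased
by ubiquitous demodification. `nucspread` implements a continuous-time
Markov chain in which each nucleosome holds one modification state and at
most one bound transferase, and enzymes move by three mechanisms that can be
switched independently:

* **binding** at a designated initiation site (rate *k_on*), and release
  anywhere (*k_off*);
* **1D diffusion**: nearest-neighbour sliding at total hop rate *k_slide*
  (equal chance left/right, reflective array ends, enzymes cannot pass each
  other);
* **modification-induced recruitment**: binding at any nucleosome that
  carries the enzyme's own mark (*k_recruitment* per eligible nucleosome)
  plus catalysis of unmodified flanking nucleosomes (*k_neighbor*);
* optionally, **chromatin connectivity**: designated contact sites between
  which a bound enzyme can jump, or two enzymes exchange places
  (*k_interaction* per site pair).

On-site catalysis (U → mark, *k_transferase* = 1000 s⁻¹) is effectively
instantaneous; demodification (M → U, A → U) runs at *k_demodification* =
2.4 s⁻¹ everywhere. In single-enzyme models only the methyltransferase is
explicit and acetylation is a 2.4 s⁻¹ background reaction; dual-enzyme
models pit a methyl- and an acetyltransferase with mirror-image kinetics
against each other. All defaults derive from physical constants
(diffusion-limited association, measured 1D sliding coefficients, FRAP
residence times); see `derive_rate_table()`.

The simulator is an event-driven exact SSA (next-reaction method with an
indexed priority queue; the classical direct method is kept as an
independent cross-check) written in C++ via Rcpp. The analysis layer
computes the standard summaries: time-weighted positional profiles
(ChIP-like stationary patterns), binned activation/relaxation dynamics,
steady-state count distributions, seeding-bistability statistics, and
boundary statistics for dual-enzyme runs. Everything returns tibbles and
has `autoplot()`, `tidy()` and `glance()` methods.

This is a tool for quantitative chromatin biologists and modellers who want
to explore how binding, sliding, recruitment and long-range contacts shape
the establishment, maintenance and decay of histone-modification patterns
at single-gene scale.

## Worked example

Simulate the combined diffusion + recruitment mechanism on a 50-nucleosome
array for 200 s:

```r
library(nucspread)

m <- spread_preset("combined_single")   # k_on = k_recruitment = 2.4 s^-1
tr <- simulate_spread(m, t_end = 200, seed = 42)
glance(tr)
#>   t_end n_events n_slide n_recruit n_connect final_M final_A final_Mt final_At
#> 1   200    41044     601       604         0      41       4       42        0
```

Starting from a fully acetylated array, a single trajectory fires ~41,000
reactions in 200 s and ends with 41 of 50 nucleosomes methylated and 42
bound methyltransferases — the gene-wide silenced pattern this mechanism is
known for. `autoplot(kymograph(tr, dt = 1))` renders the position-by-time
raster of the spreading process.

The stationary pattern over a replicate ensemble (time-weighted over the
final 60 % of each run):

```r
ens <- simulate_ensemble(m, reps = 20, t_end = 200, seed = 42)
positional_profile(ens)
#>   position   p_U   p_A   p_M  p_Mt
#> 1        1 0.210 0.192 0.598 0.589
#> 2        2 0.160 0.161 0.679 0.662
#> 3        3 0.140 0.144 0.715 0.699
#> ...
```

Methylation probability is high across the whole array, peaks around the
central initiation site and dips toward the reflective ends, where no
enzymes flow in from outside.

Bistable seeding — what fraction of runs establish the pattern from one or
five methylated, enzyme-bound seed nucleosomes, with no initiation influx:

```r
res <- seeding_experiment(k = c(1, 5), reps = 50, t_end = 300, seed = 42)
tidy(res)
#>   seeds reps n_high fraction conf_low conf_high mean_M_high
#> 1     1   50     41     0.82    0.686     0.914        41.5
#> 2     5   50     50     1.00    0.929     1.000        41.7
```

A single seed ignites the high-methylation state (~41 methylated
nucleosomes, time-averaged over the final 10 % of the run) in 82 % of these
replicates; five seeds never fail. The remaining runs relax to the
mark-free background — the hallmark of stochastic bistability.

A thin command-line front end ships in `inst/cli/nucspread.R`
(`simulate`, `experiment seeding|relaxation`, `derive-params`).

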