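# txnfrap

Stochastic simulation and FRAP analysis of mRNA kinetics at an MS2-tagged
transcription site.

## The problem

At a tandem reporter gene array, every nascent transcript carries 18 MS2
stem-loops bound by fluorescent coat protein, so the transcription site is a
single bright spot whose signal can be photobleached and watched as it
recovers (mRNA FRAP). Recovery speed is set by transcript turnover:
elongation time plus the **retention time** — the delay between termination
and release of the finished transcript from the locus. Comparing a
3-exon/2-intron reporter (E3) with a 6-exon/5-intron one (E6) separates two
regimes: fast release (retention ≈ 50 s; E3, or E6 when splicing-factor
availability is raised by Clk1 overexpression) versus slow release
(retention ≈ 11 min; E6), with splicing completion gating release. A second,
fixed-cell readout is the intron/exon FISH ratio at the site, where splicing
efficiency appears as positional depletion of the intron signal 750 bp after
it is made (500 bp under Clk1).

`txnfrap` is for researchers who want to reason quantitatively about such
live-imaging data: it provides the forward model, the measurement model, and
the inverse analyses in one tested package.

## What's inside

* **Monte-Carlo simulator** (`simulate_frap`, `simulate_fish_snapshot`,
  `step_site`, `run_to_steady_state`, `apply_bleach`): polymerases on a
  multi-copy array with stochastic initiation, pausing, termination,
  post-termination retention and positional intron depletion; fixed-step
  Bernoulli dynamics (each rate *r* fires with probability *r·dt*),
  bit-reproducible from an integer seed.
* **Analytic oracles** (`expected_site_occupancy`, `expected_fish_ratio`):
  Little's-law closed forms — stationary occupancy
  `n_copies·init_rate·(L/v + retention)`, and the intron/exon ratio as a
  ratio of per-transcript signal lifetimes — used to validate the simulator
  in the no-pause limit.
* **FRAP analysis** (`normalize_frap`, `fit_recovery`, `select_model`,
  `compare_curves`, `fdr_adjust`, `fit_retention_time`): double
  normalization; multi-start least-squares fits of
  `y0 + Σ A_j(1 − exp(−k_j t))` with AIC model selection and mobile/immobile
  fractions; permutation comparison of replicate curve sets with
  Benjamini–Hochberg correction; retention-time retrieval by fitting the
  simulator to an observed curve on a grid.
* **Synthetic data** (`gen_frap_dataset`, `gen_fish_table`): seeded raw
  traces with acquisition bleaching, day-replicate structure and noise, and
  per-site FISH tables with lognormal channel noise — each with its ground
  truth, so every analysis has a recovery target.
* **Analysis workflow** (`analysis/01…04_*.R`): numbered drivers that
  simulate the three kinetic regimes, fit synthetic splicing-factor FRAP,
  tabulate FISH ratio predictions, and demonstrate retention retrieval,
  writing tables under `results/`.

## Worked example

```r
library(txnfrap)

gene <- build_gene("E6")                       # 6 exons, 5 introns, 18 MS2 repeats
fast <- simulate_frap(gene, kinetic_params(retention_mean = 50),  n_sites = 100, seed = 1)
slow <- simulate_frap(gene, kinetic_params(retention_mean = 660), n_sites = 100, seed = 1)
half_time <- function(cv) cv$time_s[cv$time_s >= 0][which(cv$mean[cv$time_s >= 0] >= 0.5)[1]]
half_time(fast)   # 40.5  seconds to half recovery at 50 s retention
half_time(slow)   # 375   seconds at 660 s retention

# retrieve the generating retention time from the "observed" slow curve
fit <- fit_retention_time(slow, gene, kinetic_params(),
                          retention_grid = c(50, 660), n_sites = 100, seed = 2)
fit$table
#>   retention_s          sse
#> 1          50 26.344208521
#> 2         660  0.000215347
fit$best_retention
#> [1] 660

# steady-state intron/exon FISH ratio vs the analytic oracle (no-pause limit)
p <- kinetic_params(pause_on_rate = 0)
snap <- simulate_fish_snapshot(gene, p, n_sites = 200, seed = 3)
mean(snap$ratio)                 # 0.492
expected_fish_ratio(gene, p)     # 0.498
```

The two FRAP curves differ only in the retention parameter, yet half
recovery moves from ~40 s to ~6 min — the kinetic signature that transcript
release, not transcription, separates the regimes — and the grid fit
recovers the generating value with an SSE gap of five orders of magnitude.
The simulated FISH ratio sits within ~1% of its closed-form expectation.

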