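---
title: "Modeling mRNA retention and splicing kinetics at an MS2-tagged gene array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling mRNA retention and splicing kinetics at an MS2-tagged gene array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txnfrap)
```

## The system and the question

A tandem array of Tet-inducible reporter mini-genes, integrated at a single
genomic locus, produces a transcription site bright enough to follow in
single living cells: the 3'UTR of each transcript carries 18 MS2 stem-loops
that are bound by fluorescent MS2 coat protein as soon as they are
synthesized. Two constructs differ only in intron count — a 3-exon/2-intron
form (E3) and a 6-exon/5-intron form (E6). Photobleaching the transcription
site (mRNA FRAP) erases the signal of every transcript currently at the
locus; recovery then reports the rate at which bleached transcripts are
replaced by newly made, fluorescent ones.

The central kinetic quantity is the **retention time**: the delay between
transcription termination and the departure of the completed transcript from
the site. The package's working model is that splicing completion gates
release — a gene with more introns (E6) holds its finished transcripts for
minutes rather than seconds, and raising nucleoplasmic splicing-factor
availability (Clk1 overexpression, which disperses nuclear speckles) returns
E6 to fast release. The model's two regimes are a retention of 50 s (fast:
E3, or E6 with Clk1) versus 660 s = 11 min (slow: E6), with splicing
efficiency expressed positionally as depletion of an intron's signal 750 bp
after its 3' end is made (500 bp under Clk1).

`txnfrap` implements the forward model (a Monte-Carlo simulator of the
array), the measurement model (in-silico bleaching, FRAP sampling, and
steady-state intron/exon FISH snapshots), and the inverse analyses used on
such data (curve normalization, exponential fitting with model selection,
permutation comparison of conditions, and retrieval of the retention time by
fitting the simulator to a curve).

## The Monte-Carlo model

Each of `n_copies` identical gene copies (default 20, a placeholder for the
unpublished array copy number) is simulated independently within a site.
Time advances in fixed steps of `dt` seconds (default 0.1 s); each
first-order rate $r$ fires within a step with probability $r\,\mathrm{d}t$,
the Bernoulli approximation of exponential waiting times. A validation guard
keeps every such probability at or below 0.1 so the discretization error in
the implied waiting time stays below ~5%.

Per step and per copy:

* **Initiation** at `init_rate` (default 0.05 s^-1 per copy), gated on a
  clear promoter-proximal footprint (35 bp, the approximate polymerase
  footprint; the source system's value is unpublished).
* **Pausing**: elongating polymerases enter a paused state at
  `pause_on_rate` (0.01 s^-1) and leave it at `pause_off_rate` (0.1 s^-1),
  modeled per unit time, not per bp.
* **Elongation** at `elong_rate` (55 bp/s, a mid-range mammalian Pol II
  speed), clamped so a polymerase never comes within one footprint of the
  polymerase ahead and stops at the gene end.
* **Termination**: a polymerase at the gene end releases its transcript at
  `termination_rate` (0.2 s^-1); the transcript then stays at the site for
  the retention draw — a fixed `retention_mean` by default (the regimes are
  quoted as single times), or exponential with that mean, since the true
  dispersion is unknown.

Signals are pure functions of polymerase position: the MS2 signal is the
fraction of the MS2 region transcribed; an intron's probe signal exists from
the crossing of its 3' end until the polymerase is `splice_depletion_bp`
further (binary accrual); the exon-probe signal appears when the probe
target's 3' boundary is crossed and persists until the transcript leaves.
Bleaching instantaneously marks every transcript's current MS2 signal as
dark; the free coat-protein pool is assumed unbleached and in excess, so new
loops are always bright.

All randomness comes from a self-contained 64-bit splitmix stream stored in
the site state, so every operation is bit-reproducible from an integer seed
and independent of R's session RNG.

## Steady state and burn-in

`run_to_steady_state()` applies an explicit convergence test: two
consecutive windows, each five expected dwell times long, must agree in mean
total MS2 signal to 5% (relative). The bulk simulators (`simulate_frap()`,
`simulate_fish_snapshot()`) instead burn in for a fixed two expected dwell
times, on a stationarity argument rather than a convergence heuristic: with
initiation a Poisson process from $t = 0$ and a fixed retention, the site
occupancy at time $T$ depends only on initiations in the last dwell time, so
the process is exactly stationary once $T$ exceeds the longest plausible
transcript dwell — and twice the *expected* dwell exceeds that for every
parameter set shipped here (retention, the dominant term, is deterministic;
the stochastic transit and termination tails are small against it).

## Acquisition schedules

Two experimental schedules are packaged. Protein (splicing-factor) FRAP:
5 pre-bleach frames, then four images per 2 s — 0.5 s spacing — over 60 s.
mRNA FRAP: 6 pre-bleach frames and three post-bleach segments; the printed
protocol's first and last intervals (3 ms and 30 ms) are inconsistent with
the stated 45 s / 480 s durations and with EM-CCD frame rates, so the
default preset uses 0.3 s / 6 s / 30 s and the literal printed values are
preserved as `"mrna-frap-printed"`. Nothing downstream depends on the
choice: schedules are plain data and fully configurable. Frame times snap to
the simulation step grid.

## The analytic oracles

Two closed forms make the simulator falsifiable in the no-pause,
deterministic-elongation limit:

* **Occupancy (Little's law)**: mean transcripts per site =
  `n_copies * init_rate * (length_bp/elong_rate + retention_mean)`. The
  closed form omits the mean termination wait and the slight initiation
  thinning caused by the promoter footprint, so it is checked with fast
  termination and modest initiation rates, where both biases are well inside
  Monte-Carlo error.
* **FISH ratio**: by stationarity, each channel's expected signal is the
  common arrival rate times the signal's lifetime per transcript, so the
  expected intron/exon ratio is a ratio of lifetimes. With the simulator's
  binary accrual a probe intron lives `splice_depletion_bp/elong_rate`
  seconds (or, if the depletion point falls beyond the gene end, until
  transcript departure), and the exon probe lives from its target's crossing
  until departure (remaining transit + mean termination wait + retention).
  `expected_fish_ratio(accrual = "gradual")` adds half-length synthesis
  terms approximating length-proportional probe hybridization; on the
  default geometries the two variants differ by ~10-20%, a bound the test
  suite pins down on toy genes. The default is `"binary"` because it is the
  exact expectation of what the simulator (and an event-counting image
  analysis) measures.

These oracles drive the directional predictions: the ratio rises with intron
count (E6 > E3), falls sharply when retention grows 50 s → 660 s (finished,
intron-free transcripts pile up and dilute the intron channel), and dips
only slightly when depletion shortens 750 → 500 bp.

## FRAP analysis choices

* **Normalization** is the standard double normalization:
  `(roi - background)/(whole - background)`, then division by the pre-bleach
  mean of that quotient (window: all pre-bleach frames, configurable). This
  cancels acquisition photobleaching exactly and fixes the pre-bleach level
  at 1 by construction. The source protocol's exact windowing is not
  reproduced in print; the all-frames window is the package's choice.
* **Exponential fitting** minimizes least squares for
  $y_0 + \sum_j A_j(1 - e^{-k_j t})$ on post-bleach frames. Bi-exponential
  SSE surfaces are multimodal, so fitting is multi-start: rates on a
  log-spaced grid ($10^{-3}$–$1$ s$^{-1}$, 5 points per component),
  amplitudes and $y_0$ from a linear solve at fixed rates, then
  Levenberg–Marquardt refinement from the three best starts, rates bounded
  positive. The bleach-depth intercept $y_0$ is fitted rather than pinned to
  the noisy first post-bleach frame. The plateau is unconstrained, with a
  warning above 1.05 (per-site normalization makes a slight overshoot
  expected — the mean of ratios exceeds the ratio of means).
* **Model selection** prefers the bi-exponential only when AIC improves by
  at least 2 *and* the rates are at least 3-fold apart; the source analysis
  states only the conclusion (two components), so both thresholds are the
  package's own, chosen to avoid rewarding degenerate equal-rate fits.
* **Condition comparison** uses a permutation test on the mean absolute
  difference between condition mean curves over the shared post-bleach grid
  (linear interpolation, never extrapolation), with
  $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$. The original
  analysis fits polynomial linear mixed models; that is replicate-level
  standard statistics requiring raw per-experiment data, and the permutation
  test is the package's documented substitution with the same
  Benjamini–Hochberg correction applied across contrasts.
* **Retention retrieval** is a grid search: simulate the FRAP experiment at
  each candidate retention with a matched seed and schedule, score by SSE on
  the observed frames, return the argmin (ties to the smaller retention).

## What the synthetic data emulate — and what they do not

`gen_frap_dataset()` reproduces the *structure* of the experiments: ~10
cells spread over 3 independent days (day effects as Gaussian multipliers on
recovery amplitudes, sd 5% — the real day-to-day variance is unpublished),
per-frame acquisition bleaching on both channels, and additive Gaussian
noise (sd 0.02 on the normalized scale by default). `gen_fish_table()`
applies independent lognormal channel noise (sdlog 0.2) to simulator
snapshots, keeping intensities positive and medians unbiased. Every
generator returns its ground truth, so each downstream fit has a recovery
target.

Passing tests on these data show that the pipeline inverts its own forward
model at realistic noise levels; they cannot show that the forward model
captures everything in real images (diffusion of the bleached pool,
z-drift, spot-segmentation error, cell-to-cell kinetic heterogeneity are all
absent), nor calibrate the absolute noise levels, which are placeholders.

## Problem sizes and numerical choices

The shipped studies use the sizes at which the package's own Monte-Carlo
error analysis makes the checks sharp: 200 sites per FRAP curve, 200–300
sites per FISH condition, 50 dwell times of trajectory for occupancy means,
40 seeded repetitions for the retention-retrieval study, 100–200 simulated
datasets for statistical calibration. Degenerate inputs are handled
explicitly: empty sites (zero pre-bleach signal) are dropped from FRAP
averages with a message; FISH sites with zero exon signal are dropped and
counted; the steady-state detector reports its two window means on
non-convergence instead of returning a state.

## Known limitations

* Segment lengths of the E3/E6 constructs and the array copy number are
  unpublished; the packaged geometries are stated placeholders, and every
  quantitative check is parameter-relative.
* Splicing is purely positional depletion — no spliceosome assembly
  chemistry, no splicing-factor diffusion or speckle model.
* Bleaching is instantaneous and total at the site; partial bleach profiles
  are not modeled.
* The pause model is per-time, not per-bp; the source description does not
  distinguish the two.
* The analytic FISH oracle holds only without pausing; with pausing on, use
  the simulator itself.
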