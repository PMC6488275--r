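---
title: "A probabilistic model of cell-size homeostasis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probabilistic model of cell-size homeostasis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdivsim)
```

## The model

Classical accounts of cell-size control at division are deterministic: a
cell divides when it reaches a target size (*sizer*), when it has added a
fixed increment since birth (*adder*), or after a fixed time (*timer*).
`pdivsim` implements a fourth, probabilistic account — the **P(Div)
model** — in which a growing cell has, at every minute, a probability of
committing to division that increases with its current size. That
dose-response is a three-parameter Hill function

$$ p(s) \;=\; p_{\max}\,\frac{s^{n}}{EC_{50}^{\,n} + s^{n}}, $$

with $p_{\max}$ the per-minute probability on the plateau, $EC_{50}$ the
size at half-maximum, and $n$ the Hill coefficient (how switch-like the
size sensing is). Larger cells are simply more likely to divide; no cell
carries a memory of its birth size. In fission yeast, the proposed
molecular substrate is cyclin B (Cdc13), whose level scales with size and
must cross a Wee1/Cdc25-set threshold for mitotic entry; expression noise
in the cyclin supplies the probabilistic component. The package therefore
also implements a fifth, mechanistic **cdc13 rule**, where each cell
accumulates noisy cyclin as it grows and divides on a private threshold.

All five rules run in the same discrete-time agent-based simulator
(`run_simulation()`): one step is one minute, growth is exponential
(`size * (1 + growth_rate)` per step), and division produces two daughters
of combined size `daughter_factor * division_size` split symmetrically with
Gaussian asymmetry noise. An optional septated state holds a triggered cell
at its division size, non-growing, for `septation_duration` minutes before
the split — in fission yeast, cells stop elongating at mitosis and septate
at the length at which they will divide, which is what makes snapshot
septation data informative about the division decision.

## Parameters and defaults

The defaults are the published parameter blocks of this model family, one
per rule:

| parameter | default | units | role |
|---|---|---|---|
| `growth_rate` | 0.006 | /min | exponential elongation; doubling in ~116 min |
| `n_init` | 20 (10 for cdc13) | cells | initial population |
| `t_max` | 1000 | min | simulated span |
| `init_mean`, `init_sd` | per rule (pdiv: 14, 1.4) | size units | initial-size Gaussian, truncated positive |
| `daughter_factor` | 1.05 | — | septum adds ~5% combined length |
| `asymmetry_sd` | 1 | size units | daughter asymmetry, ± the same draw |
| `septation_duration` | 0 | min | non-growing septated period (~30 physiological) |
| `min_cycle_duration` | 0 | min | optional minimal-timer element |
| pdiv `rule_params` | Hill(0.1, 14, 14) | /min, size, — | division hazard |
| adder / sizer / timer | N(6.75, 1) / N(14.5, 1.2) / N(100, 5) | size / size / min | per-cell threshold at birth |
| cdc13 | 0.07 synthesis, 0.05 noise, 0.0001 degradation, threshold 6 ± 0.3, birth level 0.7 × size | AU | cyclin accumulation |

Two conventions for the P(Div) growth rate are in circulation for this
parameter set: 0.0029/min and 0.006/min. They cannot both hold together
with the stated run-scale facts (~120-min size doubling and more than
1,000 completed cycles from 20 cells in 1,000 min): 0.0029 doubles size in
~240 min and yields only ~700 cycles. The package default is 0.006, which
is self-consistent with the rest of the defaults; 0.0029 remains one
`sim_config(growth_rate =)` away.

The division draw each minute is Bernoulli: a Uniform(0,1) variate is
compared with $p(s)$. (A "Gaussian number between 0 and 1" is sometimes
described for this comparison; it is not a defined distribution, and the
Bernoulli reading is the standard one.)

The cdc13 rule's printed constants admit four readings
(absolute vs size-proportional synthesis × amount vs concentration
threshold), and the literal combinations are mutually inconsistent: a
constant 0.07 AU/min can never reach a concentration of 6 at sizes near 7,
while an amount threshold of 6 reached from a birth level of ~4.9 gives
~16-minute cycles and no steady state. The default is size-proportional
synthesis with a concentration threshold — the one reading of the printed
constants that produces realistic ~110-minute cycles — and both switches
(`synthesis_mode`, `threshold_mode`) are explicit `cdc13_params()`
arguments.

## What the model produces, and what the slope means

With the default hazard, a run from 20 cells over 1,000 minutes completes
roughly 19,000 cycles in about a second. Because the hazard depends only on
*current* size, division size is independent of birth size; the Fantes
plot (length extension against birth length, `fantes_fit()`) therefore has
slope −1 up to sampling noise — indistinguishable from a sizer by slope
alone, though the mechanism is memoryless rather than threshold-based. The
measured stated-world values are a slope of ≈ −0.99 and a division-size
CoV of ≈ 0.120 (both confirmed against a closed-form first-passage oracle:
the survival product of the per-minute hazard along the growth trajectory
gives CoV 0.119 and exact birth-size independence).

Weaker apparent slopes (≈ −0.8) arise when the regression is contaminated
with the founder generation — initial cells are division-sized, so their
first, birth-less cycles add high-leverage points — or when growth is
slowed to 0.0029/min, which also shrinks the cycle count below 1,000.
`run_simulation()` excludes founders from the records by default
(`record_initial = FALSE`); reports of slopes near −0.85 for this model
are reproduced by exactly that contamination, not by the homeostatic
mechanism itself. The deterministic references are exact in the package:
a zero-noise sizer gives slope −1 with all division sizes in one growth
step of the threshold, a zero-noise adder gives 0, and a zero-noise timer
gives $e^{gT} - 1 = 1.006^{100} - 1 \approx +0.819$.

`sweep_grid()` varies $EC_{50}$ and $n$ with replicate-averaged outputs.
Across the default grid, mean division size scales with $EC_{50}$ at fixed
$n$, while the Fantes slope stays at or below −0.5 whenever $n \ge 7$:
the cell can retune its size set-point through the dose-response midpoint
without losing homeostasis, provided the response stays ultrasensitive.

## Estimating the dose-response from snapshots

In an asynchronous population, the septated fraction within a size bin is
the observable surrogate of the division probability at that size.
`bin_fraction_septated()` uses uniform bins (default width 1, bins with
fewer than `min_count = 10` cells dropped — sparse extreme-size bins are
otherwise dominant and their handling is not standardized), and
`fit_hill()` fits the Hill model to the per-bin fractions at the bin
*centers* by bounded nonlinear least squares. The fit is unweighted by
default (each retained bin counts equally, matching the conventional
analysis of such data); count-weighted fitting is an option.

Because a septated cell remains septated for $\tau \approx 30$ minutes,
the snapshot fraction is an *occupancy*, not a rate. At steady state the
fraction among cells of hazard $h$ is $h\tau/(1+h\tau)$
(`occupancy_from_rate()`), and `rate_from_fraction()` converts back with
either the literal normalization `fraction / tau` or the exact
steady-state inversion `fraction / (tau * (1 - fraction))`. The literal
form cannot exceed $1/\tau$, so per-minute maxima above ~0.033 with
$\tau = 30$ can only come from the steady-state inversion; both are
provided and the mode is always an explicit argument. Consequently, a fit
to septation fractions estimates the parameters of the occupancy curve:
for the default hazard its plateau is $0.1\cdot30/(1+3) = 0.75$ and its
half-plateau size is $14 \cdot (1/4)^{1/14} \approx 12.68$ — notably below
the hazard's own $EC_{50}$ of 14.

## The cyclin-threshold analysis

`threshold_analysis()` takes one per-cell table holding two conditions: a
dividing (*permissive*) population and the same strain sampled after a
brief division block (*restrictive*, emulating a temperature shift-up of a
cdc25-ts strain under which growth and cyclin accumulation continue). The
pipeline bins cells into 8 equal-width bins spanning the dividing-size
range (the sizes of septated permissive cells), estimates a per-bin cyclin
threshold as the mean of the `k = 10` brightest permissive cells in the
bin, averages valid bins into a global threshold, and computes per bin:
P(septation) (permissive), P(cyclin > threshold) (restrictive, strict
inequality), and P(overlap) — the permissive fraction inside the interval
where the two conditions' fluorescence distributions coincide, by default
[5th percentile of restrictive, 95th percentile of permissive] per bin,
clipped and always reported. Under the threshold model, P(septation)
tracks P(suprathreshold) across bins (positive correlation) and P(overlap)
runs against it (negative correlation). `decile_window_cov()` adds the
noise-transmission readout: the CoV of cyclin in a window at the first
decile of division size, against the CoV of division size itself; noisier
cyclin expression degrades both.

Choices the data do not pin down, made once and parameterized: thresholds
are estimated from the dividing condition (that is where the
about-to-divide cells are); bins are half-open on the left with the last
bin closed; quantiles use linear interpolation throughout; bins with fewer
than `k` cells are excluded from the global mean rather than padded.

## Synthetic data: what it emulates and what a green test establishes

`synth_snapshot()` and `synth_cyclin_table()` generate per-cell tables by
running the simulator to steady state (burn-in 550 min, about five mean
cycle times) with a 30-minute septated period, pooling late snapshots, and
sampling rows; measured fluorescence is the true cyclin amount times
lognormal noise of unit mean and stated CV (fluorescence is positive and
its measurement error multiplicative). They emulate the *statistical*
structure that the analyses assume — steady-state size distributions with
size-dependent septation, and size-correlated noisy cyclin in dividing
versus division-blocked conditions. They do not emulate optics,
autofluorescence, segmentation error, or the linear-plus-plateau growth
phases of real fission yeast, so green pipeline tests establish internal
consistency (generation → analysis round trips), not instrument realism.

The threshold-recovery tests use an amount-threshold cyclin world
(size-proportional synthesis 0.07 AU per size unit per minute, constant
amount threshold 80 ± 4 AU, birth level 0.7 × birth size). This is the
natural recovery world because it has a single true threshold in
fluorescence units; it behaves as an adder (the amount gained per cycle is
≈ 11.7 × the size gained) with steady-state division size ≈ 13.5 and
~107-minute cycles. With 10% measurement noise the brightest-10-of-bin
estimator, an extreme order statistic, selects jointly on measurement
noise and per-cell threshold heterogeneity and overestimates the true
threshold by ~17% (≈ 6–8% with no measurement noise, ≈ 10% at 5% noise).
That bias is a property of the published estimator, not of the generator,
and is left visible in the acceptance suite rather than tuned away.

## Numerical choices

- `hill_eval()` computes $p_{\max}/(1+(EC_{50}/s)^n)$, which is stable for
  large $s^n$; $p(0) = 0$ by convention.
- `fit_hill()` bounds the parameters ($p_{\max} \in (0,1]$,
  $EC_{50} \in (0, \max s]$, $n \in (0,100]$), starts from
  $p_{\max,0} = \max$ fraction, $EC_{50,0} =$ the bin center nearest
  half-maximum, $n_0 = 4$, and uses `nls(algorithm = "port")` with a
  bounded quasi-Newton fallback; non-convergence and active bounds are
  flagged (`converged`, `boundary`), never silent, and degenerate inputs
  (all-zero or constant fractions) are rejected up front.
- Gaussian draws that must be positive (initial sizes, rule thresholds,
  daughter sizes after asymmetry noise) are redrawn rather than clipped;
  for the symmetric daughter noise this is unbiased.
- Quartiles, deciles and percentiles use R's default linear interpolation
  (type 7); box-and-whisker summaries (`distribution_summary()`) use
  quartile boxes with whiskers to the furthest point within 1.5 IQR and
  list points beyond as outliers.
- All randomness flows from one integer seed. Derived stages (sweep cells,
  sampling, measurement noise) use `derive_seed(seed, label)`, a stable
  31-based string hash modulo $2^{31}-1$, so stages are independent but
  the whole run reproduces from a single integer.
- The CoV uses the sample (n−1) standard deviation; Fantes fits are
  ordinary least squares over completed cycles only.

## Known limitations

- No spatial or geometric cell model, no G1/S control, no nuclear
  transport; the cdc13 rule is a single-compartment accumulation model.
- The simulator's division size distribution is exactly first-passage of
  the per-minute hazard; real populations add measurement noise and
  growth-rate heterogeneity that the model does not carry.
- `sweep_grid()` summarizes homeostasis by the Fantes slope alone (more
  negative = stronger correction), the field's standard single-number
  instrument; lineage autocorrelation statistics are out of scope.
- Snapshot sampling pools cells across nearby time points, so rows are not
  fully independent draws; estimators built on them are consistent but
  their nominal binomial errors are slightly optimistic.
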