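---
title: "Measuring genome replication dynamics from copy number: models and methods"
author: "replidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome replication dynamics from copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

During S phase a replicated locus is present in two copies per cell and an
unreplicated locus in one. If a population of cells is sequenced while
replicating and compared with a nonreplicating reference, the per-window
ratio of read counts measures `1 + P(window replicated)` — a relative copy
number between 1 and 2. Everything in replidyn is built on this scale.

The framework assumes: (i) reads are uniquely mapped and pre-filtered, so
each BED record is one independent read; (ii) within a sample, reads fall
into windows approximately as Poisson counts around the local copy number
(no mappability or GC correction is attempted — regions where this fails
show up as excluded windows); (iii) replication is complete at copy
number 2, so no segmental aneuploidy.

## Windowing and the exclusion rule

The genome is tiled with fixed windows (default 1000 bp; the terminal
window of each chromosome may be shorter and its expectations are
pro-rated by actual width). A window is excluded from a profile when
either sample mapped fewer than one quarter of its expected reads — the
expectation being each sample's own total scaled by window width over
genome size. This removes repetitive or unmappable sequence, where the
ratio would be dominated by mapping artifacts rather than copy number.
Nonreplicating windows with zero reads are excluded unconditionally, so a
ratio is never formed against a zero denominator.

## Normalizations

Three normalizations correspond to the three experimental situations, and
the profile object carries its state as a tag so that they cannot be
chained incorrectly:

* **genome mean 1** (`ratioProfile()`): one multiplicative constant makes
  the unweighted mean of included windows exactly 1. This removes the
  arbitrary ratio of total read numbers. The mean is unweighted by window
  width; partial windows are rare and the effect is negligible.
* **baseline 1** (`normalizeBaseline()`): for HU, sort-seq and MFA
  profiles the unreplicated fraction of the genome defines copy number 1,
  so the profile is rescaled to pin a low quantile to 1. The default
  quantile 0 is the literal minimum; on noisy data the minimum of many
  near-baseline windows is biased low by roughly two standard deviations
  of counting noise, so for noisy profiles either a small positive
  quantile or baselining the smoothed profile is preferable (the package
  warns whenever a normalized profile exceeds 2.05, since relative copy
  number cannot exceed two genome copies).
* **bulk scaling** (`scaleToBulk()`): each time-course sample is
  multiplied by `1 + f_rep`, the bulk replicated fraction from flow
  cytometry, so the genome mean moves from 1 (G1) to exactly 2
  (completion). `fitBulk()` provides `f_rep(t)` by fitting the same
  sigmoid family as below, with asymptotes pinned near 0 and 1 and
  predictions clipped to [0, 1].

# Median replication time (Trep)

Each window's copy-number time series is fitted with

$$F[t] = c + \frac{d - c}{(1 + e^{b (t - e)})^f}$$

where `c ≈ 1` is the pre-replication level, `d ≈ 2` the post-replication
level, `b < 0` the rate (negative so the curve increases), `e` an
inflection-scale time in minutes and `f > 0` a shape/asymmetry parameter.
The time at which the window has been replicated in half the cells solves
`F[t] = 3/2` in closed form:

$$T_{rep} = e + \frac{1}{b}\ln\!\left[\left(\frac{-2(c-d)}{3-2c}\right)^{1/f} - 1\right]$$

which exists when `c < 1.5 < d` and the log argument is positive. The
closed form is verified against bisection to 1e-8 over randomized
parameter draws in the test suite.

Numerical choices: the sigmoid is evaluated in log space
(`exp(-f·log1p(exp(z)))`) so extreme arguments cannot overflow. Fitting
uses bounded Levenberg–Marquardt least squares with start
`c = 1, d = 2, b = −0.5/min, f = 1` and `e` initialized at the first
linear-interpolated crossing of 1.5; bounds are `c ∈ [0.5, 1.4]`,
`d ∈ [1.6, 2.5]`, `b ∈ [−5, −0.01]`, `e ∈ [first − 20, last + 20]` min,
`f ∈ [0.1, 10]`. Fits operate on raw windowed values — smoothing before
fitting would blunt exactly the sharp origin signatures the method
resolves.

## When Trep is not reported

Trep is an interpolation of the sampled copy-number transition, never an
extrapolation. A window is masked, with a recorded reason, when:

* fewer than five usable timepoints remain (`insufficient data`);
* the series never reaches 1.5 (`never half-replicated`);
* the series is already above 1.75 at the first sample
  (`replicated before first sample`);
* the fitted crossing lands inside a sampling gap wider than three median
  sampling intervals (`transition not sampled`);
* the optimizer fails, the closed form is undefined, or the crossing
  falls outside the sampled span padded by one span length.

The gap rule matters whenever sampling is irregular, e.g. a dense series
through mid S phase plus one late completion point: windows whose
transition falls inside the late void have essentially unconstrained
crossings, and reporting a number there would be noise. Masked windows
split the profile into segments for peak calling, so origin calls are
never made across them.

# Measurement noise

For two samples with expected `N_A` and `N_B` reads per window, the
delta-method coefficient of variation of the window ratio is
`sqrt(1/N_A + 1/N_B)` — the floor attained when reads land in windows at
random. `covObserved()` measures the realized CoV (sample sd over mean of
the included, mean-normalized ratios) and `covSweep()` tabulates it
against window size and read depth, subsampling reads by seeded
permutation so that depth fractions are exact and reproducible. At 1000
reads per window in both samples the floor is `sqrt(2/1000) ≈ 4.5%`,
halving when both depths quadruple.

# Fourier smoothing

Where display or noisy designs (MFA) require it, profiles are smoothed by
removing all Fourier components with wavelength below a cutoff (default
20 kb — origin-scale features span tens of kb; exposed as a parameter,
and required to be at least twice the window size). Per chromosome:

1. the terminal 5 kb are set aside — they keep raw values and are flagged
   `not smoothed`, since a transform would wrap artifacts around the ends;
2. short runs of excluded windows (up to 5) inside the interior are
   linearly interpolated for the transform and re-masked afterwards;
3. the interior segment is extended by its own mirror image (an even
   extension), transformed, filtered, inverse-transformed and truncated
   back.

The even extension makes the filter an exact orthogonal projection:
smoothing is idempotent, linear, preserves the interior mean and never
increases the interior sum of squared deviations — all tested as exact
properties. These hold on the smoothed interior of profiles with uniform
data density; where long exclusion runs (more than 5 consecutive
windows, dilated by two windows on each side) force raw values back into
the output, a second pass sees a slightly different boundary and exact
idempotence no longer applies. Those regions are flagged rather than
dropped so that downstream peak calling can still see the raw data.

# Peak calling and origin matching

`peakdet()` is the classic alternating extremum scanner: a running
maximum is confirmed once the signal drops more than `delta` below it,
then a minimum is sought, confirmed on a rise of more than `delta`, and
so on; ties resolve to the earliest index. The default
`delta = 0.1` on the copy-number scale is about 2.2 counting-noise
standard deviations at 1000 reads/window; on a Trep track `delta` is in
minutes. Origin calls are maxima of copy-number profiles and minima of
Trep tracks (`invert = TRUE`). Peak positions are window centers;
sub-window refinement is deliberately out of scope. `matchToOrigins()`
assigns each call to the nearest known origin on its chromosome
(equidistant ties to the leftmost) and reports the median absolute
distance; `peakHeightVsTime()` pairs HU peak heights with Trep to expose
the activation-time dependence of synthesis under HU.

# Comparing two profiles

`compareProfiles()` tests each jointly included window for a difference
between two conditions. The variance of each mean-normalized ratio is
propagated from Poisson counting error,
`var(ratio) ≈ ratio² (1/n_rep + 1/n_nonrep)`, giving
`z = (A − B)/sqrt(var_A + var_B)` and a two-sided normal p-value,
thresholded at 0.001 and 0.01. No multiple-testing correction is applied
by default — the per-window flags at raw thresholds are the display
convention — but Benjamini–Hochberg adjusted p-values are available.
Because a genuine change in origin activity alters a contiguous replicon
whereas counting error flags isolated windows, `flaggedRuns()` reports
maximal runs of at least 5 flagged windows (bridging single-window gaps);
the fraction of flagged windows with `A > B` is reported as a diagnostic
for systematic (e.g. sorting-purity) biases. Note that when one origin's
firing is delayed, forks from flanking origins rescue the replicon edges,
so the physically changed region — and hence the flagged run — is
narrower than the full midpoint-to-midpoint replicon.

# The simulator

`ReplicationModel` is the ground truth: per origin a position, a mean
firing time, a firing-time standard deviation (normal, truncated at
zero by redrawing) and a licensing competence; one fork velocity; and an
S-phase interval on the same clock as the firing times. In each simulated
cell every origin is licensed independently with its competence (cells
left with an unlicensed chromosome are redrawn and counted), and the
replication time of position `x` is the earliest arrival
`min_i (T_i + |x − x_i| / v)` over licensed origins. Experiment kinds
reduce the per-cell times to expectations:

* **timecourse** at `t`: `1 + P(t(x) ≤ t)`; the true bulk fraction is the
  same probability averaged over positions, so genome mean and bulk
  scaling are consistent by construction;
* **sortseq**: S-phase cells uniform over S-phase progression, giving
  `1 + E[clip((sEnd − t(x))/S, 0, 1)]` — affine in `t(x)` for
  deterministic firing, which is what makes sort-seq copy number a linear
  Trep proxy;
* **mfa**: the population mixture `f_G1·1 + f_S·sortseq + f_G2·2`,
  rescaled so the latest-replicating baseline is 1;
* **hu**: `1 + P(covered)`, where a licensed origin fires only if its
  slowed activation time `huTimeScale · T_i` is reached within the
  exposure `tHU` (default 60 min), and then synthesizes
  `vHU (tHU − huTimeScale · T_i)` bp to each side (`vHU` default
  50 bp/min). The firing-time dilation is this package's model choice:
  hydroxyurea depletes dNTPs, which both stalls forks and progressively
  delays later origin activation. Without it, every origin would
  saturate its window at copy number 2 and peak heights would carry no
  activation-time signal; with it the simulator reproduces the observed
  phenomenology — a range of peak heights below 2 that falls with
  activation time. These HU parameters are calibration knobs, not
  measured quantities.

Sequencing is a multinomial draw of the sample's total reads over windows
with probabilities proportional to copy number times window width;
`makeDataset()` additionally scatters each window's reads uniformly
within the window and writes BED/chrom.sizes/truth files so the
command-line interface can run on simulated data. Every stochastic
function takes an explicit seed and is byte-reproducible.

What the simulator deliberately does not emulate: mappability and GC
biases (uniform window weights), read-level overdispersion beyond
multinomial sampling, paired-end structure, fork stalling or rate
variation outside the HU mode, replication-timing heterogeneity between
cell subpopulations, and sorting impurities. Passing recovery tests on
simulated data therefore demonstrates the correctness of the estimators
under the stated measurement model, not robustness to real-data
artifacts — on real data the exclusion rule and the not-smoothed flags
are the main guards.

## Default study conditions

The packaged `exampleModel()` is two 1-Mb chromosomes with ten origins
each (~100 kb spacing with fixed jitter), fork velocity 1.5 kb/min, an
S phase spanning 20–50 min after release, firing means uniform over
27–40 min with 2.5 min standard deviation, and full competence. Firing
means start at 27 min so that origin-window transitions fall inside a
sampling grid beginning at 25 min; with 100 kb spacing and 1.5 kb/min
forks, inter-origin midpoints replicate after the 50-min sample, which is
exactly the situation the `transition not sampled` mask exists for.
Population expectations use 4000 simulated cells by default, keeping
Monte-Carlo noise well below counting noise at the depths studied
(~1000 reads/window). Test problem sizes are chosen at this scale —
2000 windows, 7 timepoints, 10⁵-cell oracles only for tiny probe sets —
so the full suite runs in about a minute.

# Parameters that matter

| Parameter | Where | Default | Units | Why |
|---|---|---|---|---|
| `windowSize` | `windowGrid` | 1000 | bp | resolution/noise trade-off; 1 kb resolves single origins at ≥1000 reads/window |
| exclusion threshold | `ratioProfile` | E/4 | reads | removes unmappable windows before ratios |
| `q` | `normalizeBaseline` | 0 | quantile | literal minimum; raise slightly on noisy data |
| `minWavelength` | `fourierSmooth` | 20000 | bp | shortest retained wavelength; origin-scale features |
| end exclusion | `fourierSmooth` | 5000 | bp | chromosome ends are never smoothed |
| `maxGapRun` | `densityMask` | 5 | windows | longest excluded run tolerated inside a smoothed region |
| `delta` | `callPeaks` | 0.1 | copy number | ~2.2× counting-noise sd at 1000 reads/window |
| significance | `compareProfiles` | 0.001/0.01 | p-value | display thresholds; BH optional |
| `forkVelocity` | model | 1500 | bp/min | typical eukaryotic replication fork |
| `tHU`, `vHU`, `huTimeScale` | HU mode | 60, 50, 3 | min, bp/min, — | calibration of origin-limited synthesis under HU |
| `nCells` | expectations | 4000 | cells | Monte-Carlo noise ≪ counting noise |

# Known limitations

* The Poisson/delta-method error model ignores overdispersion from
  library preparation; on real data the null flag rate at p < 0.01 may
  exceed 1%, and the BH option or wider thresholds should be used.
* Trep requires the transition to be sampled; designs with a single late
  timepoint cannot recover late-replicating regions, and the package
  masks rather than guesses (the masks state why).
* The bulk-curve sigmoid family tracks flow-cytometry S-phase
  progressions well when replication kinetics are reasonably homogeneous;
  genomes with very sparse origins produce long late tails that the
  family smooths over by a few percent.
* Peak positions are quantized to window centers; distances below half a
  window are not meaningful.
* The five-parameter sigmoid is one of several plausible per-window
  kinetic models; alternative fits (analytic fork models, mixtures) are
  out of scope.
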