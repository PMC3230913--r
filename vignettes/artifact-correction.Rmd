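---
title: "Detecting and correcting spatial artifacts on oligonucleotide arrays"
author: "arrayClean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting spatial artifacts on oligonucleotide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arrayClean)
```

## The problem

High-density oligonucleotide chips measure each transcript with a probe
set of 8–20 features scattered over (or, on older designs, packed into a
block of) a large 2-D grid.  Physical damage — a scratch from handling, a
salt streak from uneven drying, a bubble in the hybridization chamber —
corrupts a spatially contiguous region of one chip.  Two things then go
wrong downstream.  First, probe summarization methods treat probes as
spatially independent; they shrug off a single bad probe but are defeated
when several probes of a set fail together, as they do under a compact
artifact.  Second, quantile normalization forces every chip's intensity
distribution onto a common reference; a chip whose distribution has been
distorted by an artifact drags that reference with it, so one damaged chip
warps every clean chip in the batch.

arrayClean addresses both: it finds artifact regions using their spatial
coherence across the batch, excludes them from normalization, and replaces
them with model-based estimates before expression is summarized.

## Data model

A batch is a `ChipSet` — a `SummarizedExperiment` whose rows are the grid
cells of one chip design (rownames `"x:y"`, 0-based, x = column) and
whose columns are chips, with one strictly positive assay `intensities`.
A `ProbeLayout` maps assigned cells to probe sets; unassigned cells are
background: they are scored and normalized like any probe but excluded
from expression modeling.  Perfect-match and mismatch probes are treated
identically throughout (no PM−MM differencing); the `isMismatch` flag is
carried but never consulted by the numerics, and a unit test asserts it
has no effect.

Within probe set *p*, observed normalized intensities follow the
multiplicative model

$$x_{b,p,j} = \theta_{p,j}\, a_{b,p} + \varepsilon_{b,p,j},$$

with gene expression $\theta$ per chip *j*, probe affinity $a$ per probe
*b*, and additive error.  Collecting the probe set into the $N \times
B_p$ matrix $X_p$, the Frobenius-optimal rank-1 fit is the leading
singular triplet: $\theta_p = s_1 u_1$, $a_p = v_1$.  Signs are flipped
so the affinity sum is positive (for positive data the leading singular
vectors are nonnegative by Perron–Frobenius); then both vectors are
rescaled by the geometric mean of the affinities, giving
$\mathrm{geomean}(a_p) = 1$ so that $\theta$ lives on the intensity
scale.  Expression tables report $\ln\theta$.

## Variance scoring

The score of probe location *g* on chip *j* asks whether that chip's
value could have come from the other chips' distribution at the same
location — in the spirit of a t-test.  With $S$ the set of unmasked log2
intensities at *g* on the other chips:

$$z = \frac{y_{gj} - \operatorname{mean}(S)}
           {\max(\operatorname{sd}(S), \sigma_{\min})},
\qquad h = |z|\sqrt{\tfrac{n-1}{n}},\quad n = |S|.$$

Masked probes still *receive* scores but never *serve* as reference, so a
real artifact on one chip cannot manufacture phantom artifacts on clean
chips ("ghosting").  The attenuation $\sqrt{(n-1)/n}$ discounts scores
estimated from few reference chips.  The floor $\sigma_{\min}$ is 0.01
times the batch median of $\operatorname{sd}(S)$ (with an absolute
epsilon fallback for degenerate all-constant batches): it is
scale-relative and only prevents division blow-ups at near-constant
locations.  Locations with $n < 2$ are undefined and excluded everywhere
downstream.  Batches of 3 or fewer chips are refused outright — the
reference distribution cannot be estimated — and batches under 6 chips
warn: resolving power grows with batch size and with how similar the
samples are.

**What the scores are computed on.**  Scores use log2 of
*median-scale-normalized* intensities (each chip divided by the median of
its unmasked probes), not the quantile-normalized output.  This is a
deliberate design choice.  Quantile normalization is rank-preserving
within a chip: a multiplicative artifact sitting at a chip's rank
extremes — say a 10x region applied to probes that were already among the
chip's brightest — is mapped straight back onto the reference range, and
no score computed downstream of the rank map can see it.  In measured
runs this made the brightest tail of a strong artifact permanently
invisible and halved the log contrast of intensity-lowering artifacts.
Median scaling removes global chip brightness (the legitimate target of
between-chip normalization) without redistributing values within the
chip, so artifact contrast reaches the score intact.  The cost is that
scoring no longer benefits from shape equalization across chips; for
batches from one platform and protocol — the intended input — shape
differences are small relative to artifact effects.

## Segmentation

A probe is flagged as artifact iff both: (1) at least `fMin` (default
0.5) of the defined probes in the `window`x`window` square centered on it
(default 15) exceed the region threshold, and (2) its own score exceeds
the probe threshold.  Windows are clipped at chip borders and the
fraction uses the actual window population, so edge probes are not
penalized.  All comparisons are strict, so constant score fields produce
empty masks.  Isolated extreme probes fail condition (1) by construction:
single-probe defects are left for the summarization method, which handles
them well.  Masks are rebuilt from scratch every iteration rather than
accumulated, so probes misjudged in early rounds are pardoned once the
normalization stabilizes.

**Thresholds.**  `tProbe` and `tRegion` (defaults 0.995 and 0.95) are
quantile levels interpreted in one of three modes.  The default,
`robust`, calibrates a half-normal null from the batch: since $h$ is
approximately $|N(0,1)|$ for clean data, the null scale is estimated as
$\mathrm{median}(h)/\Phi^{-1}(0.75)$ and the cutoff for level $q$ is
$\hat\sigma\,\Phi^{-1}((1+q)/2)$.  The median ignores the upper tail, so
the calibration holds even when an artifact occupies a sizable share of
the batch's scores.  The alternative `empirical` mode takes the levels as
batch quantiles of $h$ itself; it is provided for comparison but has a
structural flaw the robust mode exists to fix: a large artifact occupies
the top tail, pushes the 99.5th percentile into its own score range, and
thereby caps flagging at 0.5% of probes regardless of the artifact's true
extent — it masks itself.  `absolute` mode uses the values as raw
cutoffs for full manual control.

## Artifact-aware quantile normalization

Each chip contributes its *unmasked* sorted intensities, placed at
plotting positions $(r - 0.5)/m$ and linearly interpolated onto the
common level grid $(k - 0.5)/K$ ($K$ = grid cells per chip, flat
extrapolation at the ends); the reference is the across-chip mean at each
level.  Unmasked probes then receive the reference value at their
unmasked-rank position, ties sharing the mean of their tied reference
values.  Masked probes are pushed through the chip's monotone
piecewise-linear map learned from the (unmasked original → assigned)
pairs: they stay on the common scale for visualization but neither shape
the reference nor the map, and imputation replaces them anyway.  With an
empty mask this reduces exactly to textbook quantile normalization
(verified against limma's implementation in the test suite).  The
iterate-normalize-score-segment loop runs 4 times by default, which
reaches a near steady state at modest cost; iteration 1 starts from the
empty mask.

## Imputation

Flagged cells are replaced via a two-step EM on each probe set: (1) fit
the rank-1 model to the current matrix; (2) overwrite flagged cells with
$\theta_p a_p^{\mathsf T}$.  Step 2 zeroes the flagged residuals and
cannot increase the Frobenius error; step 1 is the global minimizer given
the data; so the unmasked-cell residual norm is non-increasing and
bounded below — the iteration converges (the classic SVD-imputation
argument; the package asserts the monotonicity at every iteration).
Flagged cells start at the per-probe mean of unmasked values, falling
back to the chip mean, then the global mean.

Convergence is declared when the *relative change* of the unmasked
residual norm drops below `tol` (default `1e-8`) — matching the monotone
bounded error argument — with a cap of `maxIter` (default 100), past
which the result is returned with a warning and `converged = FALSE`.
Two numerical facts matter here.  The iteration converges linearly at a
rate set by how well the masked cells are anchored by their row and
column neighbors; for probe-set matrices with the dominant rank-1
structure the model assumes, convergence lands comfortably inside 100
iterations (measured maximum 67 under the simulator's default
conditions).  For weakly anchored masking patterns — a probe masked on
most chips, or the minimal 2x2 single-cell completion — the rate
approaches one and thousands of iterations may be needed; callers doing
exact matrix completion should raise `maxIter` (the tests use up to
20000).  A probe masked on every chip takes its affinity from the
converged fit; a probe set masked everywhere on one chip still yields a
model-consistent $\theta$ for that chip.  Both are extrapolations and
the QC report's coverage warnings are the guard against leaning on them.

## The simulator

`simulateBatch()` draws from the same multiplicative model the pipeline
fits, which makes every stage testable end to end with known ground
truth.  Defaults define the study conditions used throughout the test
suite and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| grid, sets | 64x64, 500 sets x 8 probes | ~4000 assigned cells, rest background |
| `nChips` | 10 | comfortably above the small-batch warning threshold |
| `affinitySd` | 0.5 | lognormal spread of probe affinities (geomean forced to 1 per set) |
| `exprSetSd` | 1.0 | lognormal spread of baseline expression across genes |
| `exprChipSd` | 0.15 | chip-to-chip expression variation per gene: a replicate-like cohort of similar samples, the setting the method is designed for |
| `chipScaleSd` | 0.1 | global per-chip brightness, removed by normalization |
| `noiseSd` | 0.05 | additive Gaussian noise, sd proportional to the model value |

Insults are multiplicative and parameterized: disks (`injectDisk`,
membership by Euclidean distance of probe centers to a real-valued
boundary, ≤ comparison; centers constrained so at most half the radius
leaves the chip), rotated ellipses (`injectEllipse`; factor < 1 is a
"black hole", > 1 a "hot spot"), and the chip-thirds protocol
(`injectThirds`: first third of rows x0.5, last third x10) whose altered
chip acquires the characteristic trimodal intensity distribution that
makes naive quantile normalization warp the clean chips.  The thirds
partition is by rows by default and configurable to columns.  Every
injector returns the exact altered footprint, cross-checked against
brute-force enumeration in the tests.

What the simulator does *not* emulate: probe-sequence (GC) affinity
structure, RNA degradation gradients, scanner optics, or batch effects
between labs.  Passing tests demonstrate correctness of the algorithms
under the stated model, not performance on any particular real dataset.

## Evaluation harness

`expressionError()` is the pooled mean absolute difference between two ln
expression tables — the standard summary of artifact damage (akin to
average relative error on the linear scale).  `rocAuc()` sweeps a
threshold over |score| and returns the trapezoidal AUC, equal to the
Mann–Whitney concordance with ties counted one half (asserted against a
pairwise-enumeration oracle); with `maxFp` set, the curve is truncated at
that false-positive count and the area normalized by
`maxFp * positives`, a stated convention that keeps capped values
comparable across runs.  `sweepExperiment()` crosses insult sizes and
magnitudes with pipeline variants over seeded replicates (3 by default)
and tabulates errors for plots with across-replicate error bars.

## Numerical and design notes

- **Determinism.**  The core pipeline has no random step; reruns with the
  same inputs produce byte-identical outputs.  All simulator randomness
  flows from one integer seed.
- **Ingest.**  Intensities ≤ 0 are clamped to the chip's smallest
  positive value with a warning — the model and the log domain require
  positivity.  Only the CEL version-3 text dialect is parsed and written
  (bit-exact round trips, byte-identical rewrites); binary CEL variants
  and proprietary chip-description formats are out of scope, with a
  plain layout TSV standing in for the latter.
- **Cleaned output scale.**  Cleaned CEL files and matrices contain
  post-normalization, imputed intensities, and are documented as such.
- **QC guidance.**  Chips with more than 50% artifact coverage are
  reported for removal — beyond that point the output leans more on
  imputation than measurement.  This is also an honest boundary of the
  detector itself: an artifact covering about half a chip makes the
  chip's own scale estimate ambiguous (which half is "normal"?), and
  segmentation can lock onto the complement.  Within the ≲30% coverage
  regime the method targets, detection is accurate (see the acceptance
  numbers).
- **Defaults were chosen once** from the considerations above and are
  config-overridable; the acceptance script reports what the pipeline
  measures at these settings, problem sizes as in the table (6–10 chips,
  64x64 grids, 500 probe sets).

## Limitations

Artifacts are assumed multiplicative and spatially coherent; diffuse
noise without spatial structure is intentionally invisible here (and is
the province of other QC metrics).  Detection power falls with
chip-to-chip biological spread — for heterogeneous cohorts the scores'
null widens and subtle artifacts (< ~1.5x) fade below the thresholds.
Scoring on median-scaled data assumes chips share a distribution shape up
to scale; strongly shape-divergent batches (mixed platforms, mixed labs)
violate that and should not be combined in one run.  The rank-1 model
ignores probe-specific saturation and background; it is the
summarization-neutral core, not a replacement for richer expression
models downstream.
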