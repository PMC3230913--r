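# arrayClean

Spatial artifact detection and correction for batches of Affymetrix-style
high-density oligonucleotide microarrays.

Physical mishaps — scratches, salt streaks, bubbles, uneven drying or
hybridization — corrupt spatially contiguous regions of a chip.  Probe
summarization methods detect isolated outlier probes well, but large
coherent artifacts defeat them, and quantile normalization makes matters
worse: one damaged chip warps the reference distribution and with it every
clean chip in the batch.  arrayClean is for analysts preprocessing batches
of probe-level array data (new or archived) who want artifact-damaged
regions found, set aside during normalization, and replaced with
model-based estimates before expression values are computed.

## Method

For a batch of `N` chips sharing one probe grid, the pipeline iterates
(default 4 rounds), starting from an empty artifact mask:

1. **Artifact-aware quantile normalization.**  Each chip's unmasked
   intensities define its empirical quantile function; the reference is
   the across-chip mean of those functions, and every chip is rank-mapped
   onto it.  Masked probes neither shape the reference nor the map — they
   are carried through the chip's monotone normalization map and later
   replaced.
2. **Variance scoring.**  For probe location *g* on chip *j*, with *S*
   the unmasked log2 intensities at *g* on the other chips
   (scale-normalized; see the methods vignette),

   *z* = (*y<sub>gj</sub>* − mean *S*) / max(sd *S*, floor),
   *h* = |*z*| · √((n−1)/n),  n = |S|,

   a leave-one-out test of whether the chip's value belongs to the other
   chips' distribution at that location, attenuated for small reference
   sets.
3. **Sliding-window segmentation.**  A probe is flagged as artifact iff
   its own score is high **and** at least half of the probes in the
   surrounding window (default 15×15) have high scores — so spatially
   coherent damage is caught while isolated outliers, which downstream
   summarization handles well, are deliberately left alone.  Masks are
   recomputed from scratch each round, so probes misjudged early are
   pardoned later.

After the final round, each probe set's intensities are modeled
multiplicatively,

  *x<sub>b,p,j</sub>* = *θ<sub>p,j</sub>* · *a<sub>b,p</sub>* + *ε<sub>b,p,j</sub>*,

with expression *θ* and probe affinities *a* (geometric mean constrained
to 1) obtained from the leading singular triplet of the probe-set matrix —
the Frobenius-optimal rank-1 fit.  Flagged cells are imputed by a two-step
EM: fit the model, overwrite flagged cells with *θaᵀ*, repeat; the
unmasked residual norm is non-increasing, so the loop converges.  Outputs
are cleaned probe intensities (TSV and per-chip CEL v3 text files),
natural-log expression values, masks, scores, QC report, and heat-map
images (score, mask, model-residual).

The package also ships a synthetic batch simulator with parameterized
spatial insults (disks, rotated ellipses, "black hole"/"hot spot",
chip-thirds protocols) and an evaluation harness (log-domain expression
error, ROC/AUC with optional false-positive cap) so the whole pipeline is
testable without real chip data.

## Worked example

```r
library(arrayClean)

sim <- simulateBatch(simConfig(nChips = 6, seed = 11))
sim$chipset
#> ChipSet: 6 chips on a 64 x 64 grid [raw scale]
#> chips: chip01, chip02, chip03, chip04, chip05, chip06

# damage one chip with a "black hole": 31-probe disk at x0.4 intensity
ins <- injectDisk(sim$chipset, chip = "chip01", center = c(40, 24),
                  diameter = 31, factor = 0.4)

res <- runPipeline(ins$chipset, images = FALSE)
round(coverageFraction(res$mask), 4)
#> chip01 chip02 chip03 chip04 chip05 chip06
#> 0.1631 0.0000 0.0000 0.0000 0.0000 0.0000
```

Only the damaged chip is flagged (16.3% of its probes; the true disk
covers 18.3%), and the detected mask overlaps the true footprint with
Jaccard 0.889.  Correction pays off in the expression estimates: against
the insult-free batch, the pooled mean absolute difference in ln
expression is 0.0073 with the full pipeline versus 0.0393 with plain
quantile normalization and no artifact handling — the insult's damage cut
by ~5x.

```r
res$expression[1:3, 1:4]      # natural-log expression, probe sets x chips
#>          chip01   chip02   chip03   chip04
#> ps0001 7.615510 7.745776 8.151651 7.863413
#> ps0002 5.929466 5.678471 6.122909 5.873995
#> ps0003 6.260789 6.252721 6.572359 6.265038
```

A shell front end with `run`, `simulate` and `evaluate` subcommands is
installed at `inst/exec/arrayclean`:

```sh
Rscript inst/exec/arrayclean run --layout layout.tsv --cel celdir --out results
```

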