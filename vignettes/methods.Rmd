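---
title: "Methods: quantifying and mapping cell-to-cell expression dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and mapping cell-to-cell expression dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodisp)
```

## The problem

Two cell populations can share the same mean expression of a surface protein
and still differ in how widely expression varies from cell to cell. We call
the coefficient of variation (CV = sd/mean) of the single-cell distribution
the *variability* of expression, and the part of variability that is not
explained by the mean — the residual of a local regression of CV on mean —
the *dispersion*, written CV|mean. `cytodisp` implements a complete pipeline
for estimating these traits from flow-cytometry acquisitions of immunostained
cell lines, describing bimodal distributions with a two-component Gaussian
mixture, verifying the clonality of a cell line from CDR3 amplicon reads, and
testing whether a cis-acting DNA variant is associated with dispersion at
fixed mean.

Because raw cytometry from a cohort is bulky and external, the package ships
a synthetic-data generator that emulates the measurement structure end to
end, so every stage is exercised and tested without downloads.

## Gating model

An acquisition yields, per event, forward/side scatter areas (FSC-A, SSC-A),
the forward-scatter pulse width (FSC-W), a DNA stain (DAPI) and one
fluorescence channel (FL, analyzed as log intensity). `run_gating()` applies,
independently within each experimental batch:

1. **Saturation bounds.** Per channel, the 5th and 95th percentiles of all
   events pooled over the batch (linear interpolation between order
   statistics — the percentile convention is not fixed by the procedure
   itself, so we use the common interpolated one). Events outside the closed
   interval on any channel are discarded; channels with a negative lower
   bound are shifted up by its absolute value so retained values are
   non-negative.
2. **Unstained events.** The first peak–valley–peak motif of the pooled DAPI
   kernel density marks the boundary between unstained debris and stained
   cells; events below the valley are dropped. Two numerical guards make
   this robust: a peak must reach 1% of the maximum density (tail wiggles of
   a kernel estimate are not peaks), and the valley must lie *below* the
   global mode — a valley to its right is the G1/G2 valley, not a staining
   boundary. If no qualifying valley exists the filter is skipped and
   logged.
3. **Cell-size gate.** The highest-density region of a 2-D Gaussian kernel
   estimate in the FSC-A/SSC-A plane containing 75% of pooled events: the
   smallest density level set whose event mass reaches the target. The
   density is evaluated on a 256×256 lattice; an event's density is its
   nearest lattice node, which makes the point-in-region test deterministic.
   On large batches the kernel estimate uses a deterministic systematic
   subsample of up to 50,000 events (the estimate converges long before
   that; `kde2d` memory grows linearly in the number of points), while the
   containment level is always computed from *all* pooled events.
4. **Doublet gate.** The same construction at 80% mass in the FSC-A/FSC-W
   plane. Doublets carry roughly doubled scatter area and DNA signal but an
   inflated pulse width, which places them outside the high-density region.
5. **G1 selection.** Per sample, cells below a DAPI threshold are retained
   as G1. The threshold is the flattest point of the density's falling flank
   right of the global mode — the first point where the first derivative
   returns to zero, i.e. the G1/G2 valley, or effectively the deep right
   tail when the distribution is unimodal. We read the published criterion
   ("minimize the first derivative") as this flattest-point rule: the
   literal most-negative-derivative point of any Gaussian-like peak sits at
   one standard deviation above the mode and would discard ~16% of G1 cells,
   which contradicts both the reported retention and the intent of keeping
   the G1 peak.
6. **Minimum events.** Samples with ≤ 1,000 events after G1 selection are
   dropped (reason `"min-events"` in the QC report).
7. **Cell-size correction.** Per sample, a robust linear model
   `FL ~ log(FSC-A) + log(SSC-A)` (Huber M-estimation, tuning constant
   1.345, ≤ 50 IRLS iterations, tolerance 1e-8) and the transform
   `FL_i <- mean(FL) + e_i` with `e_i` the i-th residual. The arithmetic
   mean of the sample's FL, not the robust intercept, anchors the transform,
   matching the printed form of the correction; with least-squares residuals
   (`method = "ls"`) the sample mean is preserved exactly.
8. **Replicate alignment.** Replicates of the same line and protein are
   registered by landmarks: up to two primary density modes per sample,
   group-consensus landmark positions, and a monotone piecewise-linear warp
   per sample (a pure shift when only one landmark is shared). Monotonicity
   guarantees rank order is preserved; a warp that would invert collapses to
   slope 1.
9. **Replicate outliers.** For groups of at least three replicates, each
   sample's K score is its mean two-sample Kolmogorov–Smirnov statistic
   against its replicate partners; samples with K above the 95th percentile
   of the batch's pooled K scores are flagged. K is computed after
   alignment (the ordering of the two steps is not fixed by the published
   description; flagging before alignment would conflate removable
   registration shifts with true irreproducibility). Pooling is per batch —
   batches never share bounds, gates or score pools.

## Dispersion traits

`summarize_samples()` computes per-sample n, mean, SD (n−1 denominator) and
CV of the processed log intensities. CV is deliberately computed on the
log scale — the scale on which the pipeline operates after correction and
alignment; the CV of logs is not the CV of raw intensities, and all traits
in this package are log-scale traits.

`fit_cv_mean_trend()` fits a lowess regression of CV on mean over all
samples of one protein (span 0.75, 3 robustness iterations; the span is a
package default, chosen as the standard lowess default, since the method
carries no published span). `dispersion_residuals()` subtracts the trend:
`cv_given_mean = cv − trend(mean)`. Outside the fitted mean range the trend
extrapolates to the nearest endpoint and flags the sample.

For bimodal proteins, `fit_gmm2()` fits the five-parameter two-component
Gaussian mixture (p1, mu1, mu2, sigma²1, sigma²2) by EM with unequal
variances: one quantile-split initialization plus five random restarts, best
log-likelihood kept, convergence when the relative log-likelihood change
falls below 1e-8 (cap 500 iterations), and a variance floor of 1e-6 × the
data variance that discards degenerate single-point components. Components
are labeled so mu1 ≤ mu2 — "first component" is otherwise ambiguous.

Line-level analysis averages replicate values per line (excluding
outlier-flagged samples), z-scores each parameter across lines and clusters
with complete linkage on Euclidean distance (`cluster_lines()`). Group
comparisons use the Kruskal–Wallis rank-sum test, pairwise dispersion
correlations use Spearman's rho, and replicate-level line contrasts use the
t-test (Welch by default; the pooled-variance variant is available because
the published contrasts do not state which was used).

## Clonality

A cell line's clonality is read from a per-read CDR3 annotation table
(produced upstream by an IgBLAST-style annotator; this package consumes the
TSV contract). Reads are kept when the CDR3 was found, the VDJ frame and top
D gene are annotated, the CDR3 peptide is at least 5 amino acids, and the
J-region translation contains the conserved Phe/Trp-Gly-X-Gly motif
(matched as the pattern `[FW]G.G`; no alignment is performed). Clonotypes
covered by a single retained read are then removed. Representativity is the
percentage of retained reads per unique CDR3 peptide.

The verdict applies the rules in their stated order with inclusive
thresholds: two or more sequences at ≥ 20% → polyclonal; else a major clone
at ≥ 80% → monoclonal; else inconclusive. The order matters only for the
boundary table (exactly 80/20), which the precedence resolves as polyclonal.
Thresholds are applied per replicate, then `reconcile_replicates()` flags
clonotypes reaching 20% in only one of two technical replicates as suspect
contamination, excludes them, and recomputes a consensus; replicates that
still disagree yield an inconclusive consensus with both calls reported.

## cis-linkage

Traits (mean, cv, cv|mean, and the five mixture parameters where relevant)
are mapped against variants within ±2 Mb of the gene's strand-aware TSS
(closed, 1-based intervals; the caller supplies the transcript start for
forward genes and the transcript end for reverse genes). Variant QC removes
duplicated entries, variants with MAF < 0.05 (computed from non-missing
genotypes) and variants failing the exact conditional Hardy–Weinberg test at
p < 0.001. The association model is a per-variant simple linear regression
of the trait on alternate-allele count (0/1/2), individuals with missing
genotype or trait dropped variant-wise; an optional genotypic model adds a
heterozygosity indicator with a 2-df F test and falls back to additive when
no heterozygotes exist. Phase is ignored (association is phase-free) and
kinship is not modeled — a documented limitation appropriate to a cohort
with at most one close relative pair.

Family-wise error is controlled by max-T permutation: the trait is permuted
(10,000 times by default), the maximum |t| across the scan's variants is
recorded per permutation, and each variant's corrected p is
`(1 + #{max ≥ |t|}) / (n_perm + 1)` — the +1 convention avoids zero
p-values and makes the minimum achievable corrected p equal to
1/(n_perm+1). Correction spans the variants of one gene × trait scan only;
BH FDR is computed per trait independently. Where a published permutation
procedure does not state its mode, max-T is the natural choice for "the
family-wise error rate across all variants".

## The synthetic-data generator

`simulate_sample_events()` draws one acquisition: log-normal scatter,
G1/S/G2 DAPI structure (G2 mode at twice G1), a configurable unstained-
debris fraction near zero DAPI, doublets built as sums of two singlets with
pulse width inflated 1.6×, and log-scale fluorescence from a one- or
two-component Gaussian mixture plus a centred linear coupling to log scatter
(so the configured mixture mean is the population mean). Fluorescence is
simulated directly on the log scale; a raw-scale export is `exp()`.

`simulate_cohort()` adds the cohort layer: biallelic genotypes under
Hardy–Weinberg proportions, one causal SNP placed at a random position in
the cis window among independently drawn null SNPs, and per-line
fluorescence parameters in which the causal allele count scales the
log-scale SD by `effect_size` per allele at strictly fixed mean
(`effect_mode = "dispersion"`), shifts the mean at fixed SD (`"mean"`),
shifts the mixture weight (`"bimodality"`), or does nothing (`"null"`).
Replicate noise is a zero-mean Gaussian shift of the component mean
(SD 0.02 by default) emulating culture/staining day effects. Defaults —
48 lines, 6 replicates, 20,000 events, base mean 5, base CV 0.12, MAF 0.3 —
mirror a realistic cohort design of this kind. The magnitude of a real
dispersion QTL is not published for this system; the default 1.5× SD per
allele is an implementer-chosen power-analysis setting and is labeled as
such.

`simulate_cdr3_reads()` draws multinomial clone counts at planted
frequencies and generates a `noise` fraction of reads that each violate at
least one downstream filter (short CDR3, missing J motif, not-found flag,
missing frame or D gene, or a singleton clonotype).

`simulate_cd23_params()` builds a *synthetic* per-replicate mixture-
parameter table for 50 lines in three planted archetypes — 3 lines with a
low bulk and right tail, 25 with a high bulk and left tail, 22 clearly
bimodal — mirroring the qualitative cluster structure reported for CD23.
It stands in for the measured parameter table, which is not redistributable
here; the clustering worked example therefore validates the averaging /
scaling / complete-linkage pipeline against a planted truth, not the
original dendrogram.

### What the generator does not emulate

Real acquisitions carry autofluorescence, spectral spillover (absent here
because single staining needs no compensation), instrument drift within a
plate, non-Gaussian scatter shapes, S-phase DAPI plateaus that blend into
G1/G2 tails, and biological covariance between size and cell-cycle phase.
Passing tests on synthetic cohorts therefore demonstrate the correctness
and calibration of the algorithms under the stated measurement model, not
performance on any particular instrument's data.

## Numerical choices and degenerate inputs

* Kernel densities: Gaussian kernel, Silverman's rule-of-thumb bandwidth,
  512-point grids (configurable). 2-D gates: 256×256 lattice.
* Percentiles: linear interpolation between order statistics throughout.
* Saturation bounds error out on a constant channel; a constant scatter
  channel downgrades size correction to a logged no-op; an unstainable DAPI
  density skips the debris filter with a logged condition.
* EM restarts that collapse a component (weight → 0 or variance below the
  floor) are discarded; if all starts collapse the fit errors.
* Warping refuses non-monotone landmark maps (slope clamps to 1) and
  aligns on the shared leading landmark when replicates disagree on
  landmark count.
* Ties at gate boundaries and channel bounds are retained (closed
  intervals).
* Permutation p-values use the +1/(n+1) convention; scans are invariant to
  variant and individual order; a constant trait yields corrected p = 1
  everywhere.

## Problem sizes used in tests

The shipped tests exercise: gating batches of 4 × 20,000 events; dispersion
recovery on a 48-line cohort at 6 replicates × 10,000 events through the
full gating chain (planted 1.5× SD effect; rank correlation with truth
> 0.8); mixture recovery on 50 datasets of 10,000 cells (median |p1 error|
< 0.02); null calibration of the max-T scan over 200 cohorts at 1,000
permutations (family-wise detection rate within the binomial band around
5%); power on 25 planted-QTL cohorts of 200 SNPs (causal variant top-ranked
in ≥ 80%); and clonality verdicts over 300 seeded read simulations plus an
exhaustive 1%-grid comparison against the rule-table oracle. These sizes
were chosen so the full suite reflects the study-scale behavior of each
stage while remaining routine to run.

## Known limitations

* FCS containers are not parsed; event tables enter as CSV with a manifest.
* The warp is a two-landmark piecewise-linear registration, a simplified
  member of the landmark-registration family used by flow-cytometry
  normalization tools; it does not reproduce any specific tool's spline.
* Kinship and population structure are not modeled in the association
  scans; cis windows only.
* The G1 gate retains early-S cells that fall below the G1/G2 valley; with
  a realistic S fraction this bounds achievable "pure G1" purity.
* CV|mean depends on the lowess span; conclusions should be checked for
  stability across spans when applied to real cohorts.
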