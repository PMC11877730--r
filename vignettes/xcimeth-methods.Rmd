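---
title: "Methods: X chromosome methylation analysis and XCI escape calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: X chromosome methylation analysis and XCI escape calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcimeth)
```

## Background and model

In XX cells one X chromosome is epigenetically silenced (X-chromosome
inactivation, XCI). A methylation array measures, at each CpG, the
fraction of methylated alleles (the beta value, in [0, 1]); in an XX
sample this is the *average* of the active X (Xa) and inactive X (Xi)
allele states, while an XY sample reports the Xa alone. The central
quantity throughout the package is therefore the sex difference in mean
methylation,

$$\Delta\beta = \bar\beta_{XX} - \bar\beta_{XY} \approx \tfrac12(m_{Xi} - m_{Xa}),$$

which isolates the Xi contribution. In most somatic tissues, genes
subject to XCI carry methylated Xi promoters (large positive
$\Delta\beta$), while escape genes do not; in the placenta the Xi is
globally hypomethylated and this coupling is much weaker. The package
provides the full tool chain needed to quantify that coupling: CpG
annotation, probe QC, region summaries by sex, an allele-balance XCI
classifier, a correlation battery, PCA/PC-PR2 covariate analysis,
per-CpG linear models, and a synthetic-data generator used to validate
every step end to end.

## Genomic annotation

All interval arithmetic is done on 0-based half-open coordinates, the
BED convention, and BED files are read verbatim. Array manifests are
1-based (the manifest convention) and shifted by −1 on ingest.
Membership of a CpG in a track is point-in-interval on the half-open
convention.

* **Promoters.** ENCODE-style promoter-like sequences (PLS) are paired
  with a gene when the PLS interval overlaps the closed ±200 bp window
  around the gene's TSS. We interpret "±200 bp" as interval overlap with
  the window rather than an edge distance because that matches the
  definition of PLS elements, which are themselves anchored on TSSs.
* **Enhancers.** Proximal enhancer-like sequences (pELS) are paired with
  genes whose TSS lies in `[start − 2000, end + 2000)`. The right edge
  is half-open so that boundary positions resolve deterministically.
* **CpG islands.** Islands are classified by the density criteria:
  high-density (HC) requires length > 500 bp, GC > 0.55 and
  observed/expected CpG ratio > 0.75; otherwise intermediate (IC)
  requires length > 200 bp, GC > 0.50, obs/exp > 0.48; anything else is
  unclassified. All comparisons are strict, so an island of exactly
  500 bp is at best IC. The HC thresholds dominate the IC thresholds,
  so every HC island also satisfies the IC clauses.
* **TSS windows.** Strand-aware upstream bands: for a `+` strand TSS at
  t, TSS200 is `[t − 200, t)` and TSS200-1500 is `[t − 1500, t − 200)`;
  mirrored for `−` strand. A CpG falling in the TSS200 band of one gene
  and the TSS200-1500 band of another is labelled TSS200 — we prefer
  the closer band, since the nearer TSS is the more plausible
  regulatory target; counting such CpGs in both windows is a defensible
  alternative that would slightly enlarge the distal band.
* **Multi-gene membership** is retained as sets (comma-separated in the
  flat table); gene-level summaries expand one row per (region, gene).

Overlap queries are delegated to `GenomicRanges`/`IRanges` after
converting to their 1-based closed convention; the test suite checks
every operation against a naive all-pairs oracle on random instances.

## Probe QC, sex inference and region summaries

A probe is dropped when the fraction of samples in which it fails —
detection p > 0.01, bead count < 3, or a missing beta — exceeds 5%
*strictly* (so 1 failing sample out of 20 is retained), or when it is on
a mask list of polymorphic/non-specific probes, or absent from the set
of mappable probes. The filter is idempotent and monotone in the
threshold.

Sample sex is inferred from median X and Y probe intensities normalised
by the median autosomal intensity, partitioned by 2-means with a fixed
seed; the cluster with higher normalised Y intensity is XY. When the
cluster centres are separated by less than 0.25 in normalised Y (as when
a cohort is single-sex) the method falls back to the fixed threshold
`y_norm > 0.5 ⇒ XY` with a warning. Mismatches against reported sex are
flagged, never auto-excluded: a mismatch can reflect a sample swap or a
karyotype anomaly, and that decision belongs to the analyst.

Region summaries compute, per region, each sample's mean and median beta
over the member CpGs (missing values ignored), then average per-sample
statistics within each sex with **equal sample weights** — weighting by
per-sample CpG coverage is an alternative we rejected because coverage
differences are a QC artefact, not a biological weight. `delta_beta` is
the XX group mean minus the XY group mean; a sex with no samples yields
a missing group mean and missing `delta_beta`. The PMD/repeat
stratification partitions CpGs into the 2×2×2 cells (chrX vs autosomal)
× (PMD vs not) × (LINE-1-or-SINE vs not); cell counts always sum to the
CpG total.

## XCI classification and the correlation battery

Allele balances are folded to `max(b, 1 − b)` on ingest so matrices on
either the [0, 1] or the [0.5, 1] scale are accepted; the thresholds are
stated on the folded (skew) scale. Per gene:

* *subject*: proportion of informative samples with balance ≥ 0.8 is
  **strictly** > 0.7 *and* median balance ≥ 0.8 (inclusive);
* *escape*: that proportion is strictly < 0.3 *and* median ≤ 0.75
  (inclusive);
* *variable* otherwise.

Genes with fewer than `min_informative` (default 5) informative samples
are reported uncalled; the floor is configurable and recorded in the
run manifest. We chose 5 because below that a single sample moves the
proportion by more than the width of the variable band.

The correlation battery computes Pearson correlations between a
region-level methylation metric (XX mean, XX median, or $\Delta\beta$)
and an XCI outcome (proportion subject or median balance), under four
gene filters: none, excluding genes with XY promoter methylation above
0.1 (which removes Xa-methylated promoters where $\Delta\beta$ is not a
clean Xi readout), restricting to promoters overlapping HC/IC CpG
islands, or both. **One BH-FDR family per battery invocation**: all
requested filter × metric × outcome combinations are adjusted jointly,
and the family size is recorded in the output, so the multiplicity
accounting is reproducible no matter how many combinations a caller
requests.

Category comparisons use Wilcoxon rank-sum tests (exact distribution
when both groups have ≤ 12 observations and no ties; otherwise the
normal approximation with tie correction). Cross-tissue concordance
reports the full 3×3 cross-classification but runs the chi-square test
on the marginal 2×3 counts-by-tissue table — with ~80 shared genes the
full cross-table has near-empty cells that invalidate the chi-square
approximation, while the marginal comparison asks the interpretable
question (do the two tissues have similar category compositions?). The
cross-table is exposed for anyone preferring the joint test.

## PCA, PC-PR2 and linear models

PCA is run on beta values with each CpG centred and scaled to unit
variance; zero-variance CpGs are dropped with a count, and missing
values are imputed with the CpG mean (PCA only — linear models use
complete cases per CpG). The decomposition is a deterministic SVD with
the sign convention that each component's largest-magnitude loading is
positive. Components whose singular values sit at numerical-noise level
(below 1e−9 of the leading one) get standardized scores of zero rather
than amplified rounding error.

PC–covariate association fits the simple model `PC ~ variable` per pair
(categorical variables as factors, k levels → k − 1 indicators, model
R² reported) with BH-FDR across the whole component × variable family.
We deliberately do not adjust these models for other covariates: the
heat-map-style screen is descriptive, and adjusted associations are the
job of the explicit linear models.

PC-PR2 keeps the smallest number of leading components reaching 90%
cumulative variance (threshold configurable), fits per component the
full multivariable model on all covariates and each leave-one-out
reduced model, takes the per-component partial R² =
(RSS_reduced − RSS_full)/RSS_reduced, and reports the eigenvalue-weighted
mean per covariate in percent. Collinear covariate sets are rejected
with the offending pair named, because partial R² is undefined when a
covariate is reconstructible from the others. The statistic is invariant
to affine rescaling of any single covariate.

Per-CpG models are **plain OLS** of beta on the predictor (gestational
age in weeks) plus optional adjustments; no empirical-Bayes variance
moderation. With ~100 samples per sex the per-CpG variance is well
estimated, the headline gestational-age result is a global null, and
the effect-size gate dominates the decision rule, so moderation would
add a dependency without changing any call. A CpG is significant only
when FDR < 0.05 **and** |slope| ≥ 0.03 beta units per week; the gate is
applied to the per-week slope (not the total gestational span), matching
how the effect is plotted and the scale on which technical-replicate
noise was characterised. Adjusting for all six cell proportions would
be singular (they sum to 1), so adjustment sets should drop one
proportion; the model rejects rank-deficient designs naming the aliased
columns.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with exported ground truth:

* Per gene, an XCI category is drawn with fractions 0.10 escape / 0.15
  variable / 0.75 subject by default — roughly the composition seen in
  cross-tissue XCI surveys, with the variable class inflated slightly so
  category-level tests always have members at the default 200 genes.
* Xa promoter methylation is low (Beta(2, 18)); Xi promoter methylation
  follows the coupling mode. In **somatic** mode it is high (Beta(18, 2))
  for subject genes, low for escape genes, and a propensity-weighted
  blend for variable genes, so methylation tracks silencing. In
  **placenta** mode it is low regardless of category and shifted down by
  a depletion term (default 0.15), reproducing an Xi that is
  hypomethylated independent of XCI status. A `custom` mode blends the
  two patterns with weight ρ.
* Measured XX beta is exactly `(Xa + Xi)/2` before noise; XY beta is the
  Xa value. Shape pairs with a zero entry are point masses (0 or 1), so
  noiseless configurations reproduce the two-allele closed form exactly:
  `m_a = 0, m_i = 1` gives XX = 0.5 and Δβ = 0.5 with zero error.
* Intergenic CpGs take trimodal base levels near 0, 0.5 and 1 (shared by
  both alleles), giving the characteristic three-mode X-chromosome beta
  histogram in XY samples; PMD blocks (runs of 50 CpGs, 30% of blocks by
  default) are shifted down by 0.15.
* Cell composition: six cell-type weights per sample from a Dirichlet
  with concentrations proportional to typical placental proportions
  (syncytiotrophoblast-dominated); per-cell-type beta offset profiles
  (SD 0.02) are applied on the beta scale before linear mixing — the
  same linearity assumption reference-based deconvolution makes.
* Measurement noise is truncated Gaussian (SD 0.05 by default, clipped
  to [0, 1]) rather than logit-normal: it is bounded, simple, and
  adequate for the rank-based and correlation-based tests downstream;
  the variance inflation of a logit-normal near 0/1 is not something
  any downstream statistic here depends on.
* Allele balances (XX samples only, informative with probability 0.8)
  are `0.5 + 0.5·Beta(18, 2)` for subject-like expression (median
  ≈ 0.95) and `0.5 + 0.5·Beta(1, 9)` for escape-like (median ≈ 0.54);
  variable genes flip between the two per sample with a per-gene
  propensity uniform on [0.3, 0.7].
* Randomness is split over named streams (metadata, methylation, allele
  balance) derived from the base seed, so one component can be varied
  holding the others fixed, and fixture export is byte-identical across
  runs.

What the generator does **not** emulate: raw probe intensities and
array chemistry, normalization artefacts, probe cross-hybridisation,
within-placenta XCI skewing, imprinting, and realistic linkage between
neighbouring CpGs (CpGs are conditionally independent given their
region). Tests passing on synthetic data therefore validate the
*computational contracts* — thresholds, overlaps, closed forms,
statistical calibration — not the biological fidelity of any particular
cohort.

## Validation scale and numerical choices

The shipped validation uses problem sizes chosen to exercise the
methods while keeping a full run in minutes: classifier equivalence on
10,000 random allele-balance matrices (up to 50 genes × 20 samples,
with threshold-tied values injected); annotation equivalence on 100+
random instances per operation against all-pairs oracles; coupling
recovery on 20 replicate pairs of somatic/placenta simulations (200
genes, 30 + 30 samples, noise SD 0.05); gestational-age null
calibration on 20 replicates of 5,000 CpGs × 100 samples with a spiked
power check (slope 0.05/week); and byte-identity of two full pipeline
runs on a packaged fixture.

Degenerate inputs are handled explicitly: empty BED files parse to
empty tables; empty intervals (start ≥ end) are parse errors naming the
line; genes below the informative floor are uncalled rather than
silently dropped; constant covariates are skipped with a note; a
constant correlation outcome is flagged degenerate rather than
returning NaN; regions without covered CpGs are omitted with a count;
windows running off a chromosome start are clipped at 0 and flagged.

## Limitations

Beta values are analysed as-is (no M-value transform), matching the
scale on which all thresholds are defined; analyses highly sensitive to
heteroscedasticity near the boundaries should transform first. The sex
inference is a two-cluster heuristic and will mislabel aneuploid
samples (e.g. 45,X) — that is what the mismatch flag is for. The XCI
classifier inherits the resolution limits of allele-specific
expression: genes with few informative heterozygotes are uncalled, and
within-sample XCI skewing is not modelled. Normalization,
cell-composition deconvolution and epigenetic-age estimation are out of
scope; their outputs are consumed as sample metadata.
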