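---
title: "CNA signatures, cross-species consistency and phenotype prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CNA signatures, cross-species consistency and phenotype prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnasig)
```

This vignette is the package's account of the statistical procedures it
implements, the choices made where the design was genuinely open, and what
the synthetic-data validation does and does not demonstrate.

## The data model

The pipeline consumes *segmented* copy-number profiles: per sample, an
ordered set of non-overlapping genomic intervals with a constant log2
copy-number ratio (`mean`), the standard output of circular binary
segmentation. Raw array normalization and segmentation are upstream of this
package. Internally all coordinates are 0-based half-open; SEG files are
read and written in the 1-based inclusive IGV dialect and BED files in the
native 0-based convention, matching each format's dominant usage. Marker
counts (`n_markers`) are carried through I/O but never used in any
computation — the minimum-marker rule belongs to segmentation.

Segmented profiles are converted to a gene × sample matrix: a gene's value
is the overlap-length-weighted mean of the segment means covering its body.
Genes with no covering segment are *missing*, and every downstream consumer
imputes them to 0 (the diploid log-ratio) through an explicit step that
logs the number of imputed cells. Imputation to 0 is a neutral choice —
absence of a segment is absence of evidence for alteration — and is the
main place where a different convention (e.g. nearest-segment extension)
could change results for sparsely covered genomes.

## Signature extraction

Principal component analysis is run on the mean-centered matrix (genes as
variables; no per-gene standardization, so high-amplitude loci dominate the
decomposition deliberately — amplitude is the signal here). Genes with
identical profiles across samples are collapsed to a single representative
first (the lowest-coordinate member), after rounding to 6 decimals; exact
float equality would be fragile and level-3-style inputs are already
rounded. Loadings are re-expanded so duplicated genes carry equal loadings.

Two conventions make the decomposition reproducible across runs and
platforms:

* **Orientation.** Each component's sign is chosen so the mean of an
  instability metric over the top score decile is at least that of the
  bottom decile (ties in scores broken by sample id; no flip on exact
  equality, so the rule is idempotent). The function default metric is the
  per-sample mean absolute CNA; the pipeline passes a true per-sample
  metric computed from the profiles.
* **Component selection.** `signature_component()` picks, among the
  leading components, the one whose top score decile carries the largest
  mean instability metric. The amplification-rich, breakpoint-dense
  signature pattern is *defined* by its association with genomic
  instability; usually this is PC1, but a cohort whose dominant variance
  direction is burden-neutral (the mutually exclusive
  amplification/deletion axis of the second signature has similar burden
  at both ends) would otherwise silently yield the wrong axis.

For the metric the pipeline uses the per-sample **breakpoint total** rather
than integrated CNA. Both track instability, but integrated CNA is a
length-weighted mean of few terms for profiles made of a handful of large
segments, so its sampling variance is large exactly for the fewer/larger-
events signature class; breakpoint counts separate the dense-breakpoint
class from everything else by an order of magnitude and are therefore the
robust operational discriminator. `run_pca()` accepts any per-sample
metric, so integrated CNA orientation remains one argument away.

A cohort's **summary signature** is the per-gene SNR,
$(\mu_1-\mu_2)/(\sigma_1+\sigma_2)$, of the top `ceil(0.10 n)` tumors by
signature score against the cohort's normal samples, divided by the maximum
absolute SNR so values lie in $[-1, 1]$. Max-abs scaling is our choice of
normalization (the alternative — rank-based scaling — would discard
amplitude); it makes the downstream consistency threshold comparable across
cohorts. A loadings-mode signature (normalized component loadings) is
available for cohorts without normals.

## Cross-cohort and cross-species consistency

The signed absolute minimum consistency score for a gene over $k$ cohort
signatures $v_1,\dots,v_k$ is

$$\mathrm{SAMCS} = \begin{cases}
\mathrm{sign}(v_1)\min_i |v_i| & \text{all } v_i \text{ strictly same sign}\\
0 & \text{otherwise.}
\end{cases}$$

A zero in any cohort zeroes the score: zero has no sign, and the strictest
reading is the one that makes conserved regions conservative. SAMCS is
permutation-invariant in cohorts and monotone non-increasing in magnitude
under cohort addition, which is what makes the sequential procedure
monotone.

**Region calling.** Maximal same-direction runs of consecutive genes with
$|\mathrm{SAMCS}| > 0.05$ (strict) become candidate regions spanning from
the first member gene's start to the last member's end (gene coordinates,
not segment coordinates — the pipeline is gene-based after matrix
construction). Runs spanning under 1 Mbp are dropped, then surviving
same-direction regions separated by under 1 Mbp are merged; regions of
opposite direction are never merged, since a consistent region has one
direction by definition. Genes absent from the shared gene space do not
break runs — they carry no cross-cohort evidence either way — so gaps are
governed by the merge rule alone. Calling is idempotent and deterministic.

**Cross-species restriction.** A second species' signature is carried onto
the reference gene space through a one-to-one ortholog map;
one-to-many/many-to-one pairs are removed first (double-counting loci would
bias consistency), and genes without orthologs are excluded rather than
zeroed — consistency is undefined off the shared space. Because the second
species' gene adjacency is different (synteny is broken) and its passenger
events are independent, same-species recurrent passenger consistency is
pruned while driver loci, altered in both species, survive.

**Sequential addition.** Cohorts enter in decreasing order of their mean
pan-cancer signature score (a balanced pooled PCA defines the ordering);
each step reports the consistency signature, called regions and genome
fraction implicated, plus an optional callback metric. A single cohort's
"consistency" is the signature itself, which anchors step 1.

## Enrichment over consistency signatures

Before enrichment, clustered isoenzymes are collapsed: genes sharing an
Enzyme Commission code whose consecutive gaps are below 100 kb chain into
one locus (chaining is transitive), represented by the member with the
largest absolute value — a tandem cluster of isoenzymes is one copy-number
locus, not several independent signals. The representative choice
(max |value| rather than, say, the first gene) preserves the locus's
strongest consistent signal.

The enrichment score is a weighted Kolmogorov–Smirnov-style running sum
over genes ranked by decreasing consistency value: set hits increment in
proportion to $|\mathrm{SAMCS}|$ (exponent 1; exponent 0 gives the classic
unweighted statistic), misses decrement by $1/(N-N_h)$, and the maximum
deviation is taken over the strictly positive prefix of the ranking only —
beyond it all genes are tied at zero and carry no ordering information. Two
degenerate cases return 0 with a flag: no positive values at all, and a set
entirely outside the positive prefix. The maximum deviation itself is *not*
clamped at zero: a set depleted from the prefix scores negative, and
clamping would put a point mass at 0 that distorts the permutation null
(the add-one p-value would then be exactly 1 for a non-trivial fraction of
null sets).

Significance comes from random gene sets of equal size drawn without
replacement from the post-collapsing measured-gene universe:
$p = (k+1)/(n_{\mathrm{perm}}+1)$ with $k$ the number of random sets at
least as extreme. The add-one form cannot return 0 (a raw fraction would
floor at $10^{-3}$ for 1,000 permutations and at 0 below it). Two
permutation statistics are exposed: the enrichment score itself (default)
and the *mean gene-set rank*. The mean-rank statistic is the more robust of
the two for ranking sets against each other, because the weighted truncated
score saturates at exactly 1 for any set whose only positive-prefix gene
happens to be the top-ranked gene; the validation suite ranks the planted
set among decoys by mean rank for this reason. Signal strength is
$-\log_{10} p$; q-values are Benjamini–Hochberg, and for sets inside a
declared redundancy family the q-value is recomputed with the other family
members removed so near-copies of a pathway cannot inflate each other.

Label enrichment along a sample ranking (mutations, subtypes) uses the
maximum absolute deviation between the labels' cumulative distribution
along the ranking and the uniform expectation, with label-shuffle
permutation p and a normalized score defined as statistic over null mean
(the natural scale-free choice given the statistic's dependence on label
count).

## Weighted gene voting

Per gene in the voting set, the weight is the Welch t-score between the
positive (signature) and negative (normal) training samples and the
decision midpoint is the mean of the two class means. A test sample's vote
is $\sum_g w_g (x_g - b_g) / \sum_g |w_g|$; multiple training cohorts'
votes are averaged. The normalization makes votes invariant to rescaling a
model's weights and comparable across models; since the target is a
continuous phenotype, votes are used as a continuous score (the midpoint
shift does not affect correlation, but keeps scores interpretable around
zero). Evaluation is Pearson correlation with an add-one permutation p over
score shuffles, plus a windowed control: Spearman correlation within
contiguous integrated-CNA windows (width 0.1, minimum 10 samples; thin
windows reported but excluded from observed and null maxima), with the
global p taken from the maximum over usable windows under score shuffles —
a family-wise "any window" null by construction. The default of 10,000
shuffles (1,000 in the bundled pipeline configuration) is a desk-scale
choice; the statistic supports arbitrarily many.

## Sample scores and test conventions

* **Integrated CNA** is $\sum_s |{\rm end}_s-{\rm start}_s|\times|{\rm
  mean}_s|$ divided by the *total assembly length*. The denominator could
  also be the covered length only; assembly length was chosen (and flagged
  here) because it keeps scores comparable between samples with different
  segment coverage, with uncovered bases contributing zero burden.
* **Breakpoints** are boundaries between consecutive same-chromosome
  segments whose means differ by more than $10^{-9}$; segmentation emits
  equal-mean splits only through marker bookkeeping, so they are one event.
* **Senescence score**: with observed cumulative log2 growth $Z(x)$ over
  passages $0..p$ and the ideal curve $Y(x) = x\max_x \Delta Z$, the score
  is $\log_2\big(\sum_{x=2}^{p}[\tfrac{Y(x)+Y(x-1)}{2}-\tfrac{Z(x)+Z(x-1)}
  {2}]/p\big)$. The sum starts at $x = 2$ as defined, so the first
  trapezoid is never counted — kept as defined, though it may look like a
  typesetting accident; changing it would shift all scores by a smooth
  amount without reordering them. A curve that always grows at its maximal
  rate has zero area gap; the score returns $-\infty$ as a distinguished
  "no senescence" sentinel, and downstream correlations exclude such
  samples with a logged count.
* **Two-group comparisons** are rule-dispatched: Shapiro–Wilk p > 0.05 in
  both groups → two-sided Student's t-test (classic equal-variance form, as
  named); otherwise Mann–Whitney U; a singleton group → z-score against the
  other group's mean and SD with a normal two-sided p. Groups of size 2
  cannot be tested for normality and fall through to Mann–Whitney. The
  dispatch is a pure function of the Shapiro p-values and group sizes.
  Note the Welch form is used for *gene weights* (t-score metric); the
  dispatched Student test is for group comparisons — two different uses.
* **Fisher's combined probability** and the **hypergeometric overlap
  tail** follow their textbook forms ($\chi^2 = -2\sum\ln p$ on $2k$ df;
  upper tail of observed-or-greater overlap).

## The synthetic study conditions

The generator is the package's study design, not a tuning surface; its
defaults were fixed once, as follows, and every stage of validation runs at
them.

| Parameter | Default | Why |
|---|---|---|
| Genome | 5 chromosomes × 100 Mbp | large enough for Mbp-scale region calling, small enough for second-scale simulation |
| Genes | ~2,000, 250 kb spacing (jittered), 20 kb bodies | gene density of a mammalian autosome at desk scale |
| Cohort | 6 signature-A + 14 signature-B + 40 near-diploid tumors + 10 normals | signature A is 10% of tumors, so the planted set coincides with the top score decile |
| Breakpoint rates /Mbp | A 0.2, B 0.02, diploid 0.02, normals 0.01 | many subchromosomal events vs few large events vs flat |
| Segment-mean noise (sd, log2) | tumors 0.05 (diploid 0.03), normals 0.02 | post-segmentation means average many probes; normals' integrated CNA stays below 0.02 |
| Driver amplification | +0.4 log2 × strength U(0.8, 1.2), three 4-Mbp regions on chr1–chr3 | a planted "glycolysis-like" set spanning three chromosomes |
| Signature-B loci | ±0.4 at one of two 2.5-Mbp loci (amp XOR del) | mutually exclusive alternate events |
| Recurrent passengers | +0.3 over three 3-Mbp regions, signature-A tumors, same species only | same-species cohorts share non-driver consistency (fragile-site/arm-level-like); this is exactly what broken synteny prunes, and without it the cross-species step would have nothing to do |
| Phenotype | α·z + N(0, σ), α = 1, σ = 0.5, z = standardized signature strength | α/σ = 2; population correlation α/√(α²+σ²) ≈ 0.894 |
| Labels | logistic(−3 + 6·strength) | ~5% background mutation rate, near-certain labelling of strong signature-A samples |
| Growth curves | 8 passages, rate 3 log2/passage, dip ∝ 30 × integrated CNA, noise 0.2 | dip-then-recover immortalization curves; protected (normal) samples stay flat |
| Second species | 10-Mbp blocks shuffled onto 4 chromosomes, 10% ortholog dropout | broken synteny with a one-to-one map |

The generator emulates the *statistical structure* the analysis assumes:
planted low-rank signature directions, Poisson breakpoints, Gaussian
segment noise, linear phenotype coupling, logistic labels. It does not
emulate marker-level aCGH noise, segmentation artifacts, clonal
heterogeneity, germline CNV contamination, or realistic gene-density and
synteny-block heterogeneity. Passing validation therefore demonstrates
that the implementation recovers what it is designed to recover under its
own model assumptions — it does not certify performance on real tumor
cohorts, where effect sizes, sharing structure and noise are less
favorable and not independent.

Validation scale (chosen as the package's study sizes): oracle equivalence
on ≥ 200 random instances per statistic; permutation-null calibration with
1,000 replicates of 199 permutations; signal recovery over 50 seeds of the
4-cohort + second-species design; structure recovery over 100 seeds; the
clustering concordance check runs on a balanced two-signature-group cohort
(20 + 20), since the deepest 2-cut of a correlation-distance Ward tree can
never isolate a 10% class from an exchangeable near-diploid majority —
correlation distance between flat profiles is ~1, so Ward splits the
majority blob instead.

## Numerical conventions

Ties in sample scores break by sample id; ties in gene ranking by gene id;
both orderings use radix sort for platform independence. The top-decile set
size is `ceiling(0.10 × n)`. Segment means are rounded to 4 decimals by the
generator (emulating level-3-style rounding) and profile round-trips
through SEG are exact. All randomness flows through a single seeded
generator per operation (`--seed`-derived child seeds in the pipeline), and
the pipeline's manifest records an MD5 per output so reruns are verifiably
byte-identical. Degenerate inputs have defined behavior: zero-spread SNR
groups return 0 or signed infinity; rank-0 matrices error; empty gene
models error; a robust chromosome maximum ≤ 0 flags the ratio as
undefined rather than returning a negative ratio.

## Known limitations

* Gene-level values ignore intragenic breakpoints' positions beyond
  length-weighting; focal events smaller than a gene body are diluted.
* Max-abs signature normalization is sensitive to a single extreme gene;
  with small normal panels the SNR denominator is noisy, which is why
  consistency (the cross-cohort minimum) rather than any single signature
  drives region calls.
* The truncated enrichment score ignores deletion-side structure by
  design; deletion enrichment requires negating the signature and
  re-running.
* The windowed-correlation control with default width 0.1 often yields a
  single usable window on desk-scale cohorts whose integrated CNA range is
  narrow; the window width is a free parameter and should be set from the
  observed burden range on real data.
* One-to-one ortholog filtering discards paralog families entirely;
  consistency at expanded loci is therefore not assessed across species.
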