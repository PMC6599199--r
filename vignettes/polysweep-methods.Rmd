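---
title: "Models and methods behind polysweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polysweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysweep)
```

`polysweep` compares a derived genetic cluster of an allopolyploid crop
against a reference cluster to locate selective sweeps and expression
diversification. This vignette explains the models the package implements,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design choices a maintainer would want
recorded. It states no empirical result beyond what the package's tests and
acceptance script themselves compute.

## The cross-population drift model

All scan statistics condition on the reference population's allele
frequency $p_1$ at a SNP. Under neutrality the object population's
frequency is modelled as

$$x \sim \mathcal{N}\!\left(p_1,\; \omega\, p_1 (1 - p_1)\right)$$

truncated to $[0, 1]$, with the truncated tail mass placed as point masses
on the boundaries (frequencies can be lost or fixed). $\omega$ is a single
genome-wide drift scale, dimensionless and $\ge 0$; it absorbs divergence
time and effective population size. Observed counts add a binomial
sampling layer: $m_2 \sim \mathrm{Binom}(n_2, x)$ over the $n_2$
chromosomes sampled.

**Estimating $\omega$.** Each polymorphic site yields an unbiased moment
numerator $(\hat p_1 - \hat p_2)^2 - \hat p_1\hat q_1/(n_1-1) - \hat
p_2\hat q_2/(n_2-1)$ (observed squared difference minus both sampling
variances). Because the drift Gaussian is clamped to $[0,1]$, the
model-implied variance of $x - p_1$ is not $\omega\,p_1 q_1$ but the
second moment of the clamped draw, which is smaller near the frequency
boundary — at $\omega = 0.1$ under the default ancestral spectrum the gap
is roughly 12 %. The default estimator therefore solves, by
one-dimensional root-finding, for the $\omega$ whose summed clamped
variances match the summed numerators. The plain ratio-of-sums form
(`truncation_correction = FALSE`) is retained; the two agree whenever the
kernel stays inside $(0,1)$. We use the pooled (ratio-of-sums) moment
identity rather than a mean of per-site ratios because per-site
denominators $\hat p_1 \hat q_1$ degenerate near the boundary and make the
site terms heavy-tailed.

**Site likelihoods.** The neutral marginal probability of $m_2$ integrates
the binomial over the drift kernel. A sweep at genetic distance $d$ from a
SNP captures a linked neutral lineage with probability
$\kappa = e^{-d/\sigma}$, where $\sigma$ (Morgans) sets the footprint
width. Given pre-sweep frequency $y$, the post-sweep frequency is
$\kappa + (1-\kappa)y$ with probability $y$ (the neutral allele rode the
sweeping haplotype) and $(1-\kappa)y$ otherwise. The sweep marginal
integrates the same drift kernel through this two-branch transform;
$\kappa = 0$ recovers the neutral likelihood identically and
$\kappa = 1$ forbids intermediate counts.

**The scan statistic.** At each grid point (default every 2 kb), SNPs
within 0.005/2 Morgans enter the window, at most 100 of them (uniform
downsampling, deterministic given the scan seed). Each SNP is weighted
$1/m_k$, where $m_k$ counts window SNPs with $r^2 \ge 0.7$ to it (itself
included), so clusters of redundant linked SNPs count once. The score is

$$S = 2\left[\max_{\sigma} \sum_k w_k \ell_k(\sigma) -
       \sum_k w_k \ell_k(\text{neutral})\right] \ge 0,$$

nonnegative because the neutral model is in the maximization. The $\sigma$
grid defaults to 12 log-spaced values in $[10^{-5}, 10^{-1}]$ Morgans —
footprints from kilobase to megabase scale at 1 cM/Mb. Weights are
computed from object-population haplotypes because the correlation penalty
targets redundant evidence in the scanned population.

## Windowed diversity, differentiation, and LD

Per-site diversity uses the unbiased pairwise estimator
$\pi_i = 2m(n-m)/(n(n-1))$; a window's value is the sum of its site
diversities divided by the **full window length in bp** (default 100 kb
windows, 25 kb step). Monomorphic or unsequenced bp therefore contribute
zero to the numerator but remain in the denominator, which is the
convention of the standard windowed tools and is what puts
transcriptome-derived values on the $10^{-5}$ scale.

F_ST uses the Weir–Cockerham (1984) variance components $a$, $b$, $c$
computed from diploid genotype counts including observed heterozygosity,
combined per window as the weighted estimator $\sum a / \sum(a+b+c)$;
windows with a zero denominator are flagged missing rather than zero.

LD decay computes pairwise $r^2$ within 3 Mb (the distance cap, MAF
$\ge 0.05$, heterozygosity $\le 0.88$ and missingness $\le 0.25$ site
filters apply to this computation only). For phased haplotypes the squared
Pearson correlation of 0/1 haplotype columns equals the classical
$D^2/(p_A q_A p_B q_B)$; for unphased input the squared genotype-dosage
correlation (Rogers–Huff style) is used instead.

The π-ratio track divides reference by object diversity per 20 kb / 10 kb
window with a pseudocount $\varepsilon$ equal to half the smallest nonzero
windowed π across both tracks: ratios stay finite and their ranking is
unchanged. Windows empty in both populations are missing.

## The candidate-region calculus

Mean composite-likelihood scores are averaged in 20 kb windows at 10 kb
step. Windows at or above the empirical 80th percentile are selected —
quantiles use "higher" interpolation and ties at the threshold are
**included**, a deterministic and conservative rule chosen because no tie
convention is standard. Selected windows that overlap or abut merge into
regions (a missing or unselected window breaks the chain); each region is
scored by its highest constituent window ("region-wise highest"), and
regions in the top 5 % of region scores are kept. The π-ratio track goes
through a single top-50 % stage. The final sweep calls are the base-pair
intersection of the two region sets; quantiles are computed genome-wide
(all chromosomes pooled), matching how genome-wide region counts are
usually reported. Whether the 5 % cut applies to regions or windows is
genuinely ambiguous in the field's usage; we cut over regions and expose
both stages' quantiles as parameters.

Gene lookup reports a gene iff its interval overlaps a region by at least
1 bp in 0-based half-open coordinates, so a gene starting exactly at a
region's end is not reported.

## Differential expression and network overlay

All accessions of a cluster are treated as replicates. The fold change is
$\log_2$ of the ratio of mean FPKM with pseudocount $\delta = 1$; the
p-value comes from a Welch unequal-variance t-test on
$\log_2(\mathrm{FPKM}+1)$. A gene is called iff $|\log_2\text{ratio}| > 1$
strictly and $p < 0.05$ strictly. This is a declared simple engine — the
package does not re-implement assembly-based DE callers; the thresholds,
replicate treatment and comparisons are the scientific content here. No
multiple-testing correction is applied by default (a Benjamini–Hochberg
option exists) because the raw-p convention is what the thresholds above
assume.

The sub-genome asymmetry test is a 1-df Pearson goodness-of-fit χ² of the
observed (DEG_A, DEG_C) counts against expectations proportional to tested
genes per sub-genome, with no continuity correction.

Network nodes are biochemical reactions owning sets of ortholog IDs; one
gene may serve several nodes (enzyme promiscuity). A node's fold change is
$\log_2$ of the ratio of summed FPKM over its DEG-mapped member genes —
sums over accessions, not per-accession means, following the "sum
expression" convention — object cluster over reference. Nodes with no
DEG-mapped members are grey ("no data"); a zero denominator with nonzero
numerator is flagged infinite and coloured red. Local clustering
coefficients are $2T/(k(k-1))$ with 0 assigned below degree 2.

## What the synthetic-data generator emulates

The generator exists so that every stage is testable against known truth.

* **Genotypes.** Ancestral frequencies follow a density $\propto 1/x$ on
  $[0.02, 0.98]$ — a neutral-like spectrum with no fixed sites, avoiding
  degenerate $p_1$. The object population drifts by the clamped Gaussian
  above — deliberately the *same* model the scan's likelihood assumes, so
  parameter recovery is a meaningful round-trip test. Haplotypes are
  independent Bernoulli draws per chromosome, emitted phased; diploids
  pair consecutive haplotypes.
* **Sweeps.** `implant_sweep()` applies the two-branch capture transform
  to the true frequencies and resamples haplotypes, so the implanted
  signal is exactly the alternative the scan models.
* **Maps.** The genetic map is linear; the default is 1 cM/Mb. The
  implanted-sweep test scenarios use 10 cM/Mb, representative of the
  gene-dense transcribed fraction of a Brassica genome where RNA-seq SNPs
  concentrate; on a 2 Mb test chromosome this gives the σ = 0.02 M
  footprint room to decay, which a genome-average map would not.
* **LD.** The base generator has no linkage; an optional Markov
  "copy-with-decay" mode (per-kb correlation ρ) exists solely to test
  LD-decay estimation. Copying can distort marginal frequencies slightly
  when adjacent frequencies differ; it is not used elsewhere.
* **Expression.** $\log_2$ FPKM is Gaussian around per-gene baselines
  ($\mathcal{N}(4, 2^2)$ by default, giving a realistic spread of
  expression levels) with cluster shifts of ±`effect_log2` for a known DE
  subset; the first cluster is the reference and carries no DE genes.

What it does **not** emulate: coalescent genealogies and realistic
haplotype structure, recombination-rate variation, allele-frequency
correlation between linked sites during drift, indels and multi-allelic
sites, read-level noise, or expression count overdispersion. Passing tests
therefore demonstrate correctness of the statistics under their own model
assumptions, not robustness to every property of real RNA-seq data.

## Numerical choices

* **Quadrature.** Site likelihoods integrate the drift kernel with a fixed
  64-node Gauss–Legendre rule placed on the kernel's effective support
  ($p_1 \pm 8$ sd intersected with $(0,1)$) plus the analytic boundary
  masses. Restricting the rule to the effective support is what lets one
  fixed rule integrate both wide and near-degenerate kernels; mass outside
  ±8 sd is below $10^{-15}$, both marginals normalize to 1 within
  $10^{-6}$, and the $\omega \to 0$ limit reproduces the binomial pmf.
* **Log floor.** Zero probabilities are floored at $\log p = -745$, the
  log of the smallest positive double.
* **Boundary clamps.** $\hat p_1$ fixed in the reference sample is clamped
  to $[1/(2n_1), 1 - 1/(2n_1)]$ because the drift variance degenerates at
  the boundary. Inside the binomial kernel, success probabilities are
  clamped away from 0 and 1 by $10^{-300}$ / $10^{-16}$ (relative error
  $< 10^{-12}$), except that nodes pinned *exactly* at a boundary
  ($\kappa = 1$) are treated as degenerate draws.
* **Determinism.** Every generator and the scan's window downsampling are
  driven by explicit seeds; the pipeline derives stage seeds from one
  global seed, and a rerun with the same configuration reproduces
  identical output checksums.
* **Problem sizes.** The shipped tests size their simulations to what the
  statistics need: 30,000 SNPs for drift-scale recovery (5 seeds per ω),
  a 2 Mb, 10,000-SNP chromosome for sweep localization (20 paired
  sweep/neutral seeds), 10,000 sites for calibration checks, 2,000 genes
  for DE recovery, and ≤1,000-element toys for exact oracle comparisons.
  LD-decay monotonicity is asserted over 1 kb distance bins within the
  first 10 kb, where the Markov generator's per-bin decay dominates the
  $r^2$ sampling floor of roughly $1/n$.

## Known limitations

* The drift scale is genome-wide; locus-to-locus variation in divergence
  (background selection, introgression) is absorbed into one ω, which
  makes sweep scores conservative where true local drift is high. An
  implanted sweep also inflates the genome-wide $\hat\omega$ slightly on
  short test chromosomes, where its footprint is a visible fraction of all
  SNPs.
* Morgan-scale parameters (`window_morgans`, the σ grid) inherit whatever
  genetic map the user supplies; with no species map available the package
  flags rather than guesses — the linear default is only a placeholder
  slope.
* Composite likelihoods ignore linkage between window SNPs beyond the
  $1/m_k$ down-weighting, as in the method family this scan belongs to;
  scores are rankable but are not calibrated likelihood-ratio statistics.
* The Welch-on-log-FPKM DE engine is a transparent stand-in with the
  stated thresholds; count-model engines will differ gene by gene,
  especially at low expression where the $\delta = 1$ pseudocount shrinks
  fold changes.
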