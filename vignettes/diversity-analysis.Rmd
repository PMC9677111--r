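---
title: "Methods: integrated diversity analysis for germplasm panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated diversity analysis for germplasm panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MarkerDiversity)
```

# Scope and model

MarkerDiversity analyses a germplasm panel characterised three ways at
once: dominant (presence/absence) molecular marker fingerprints, replicated
field-trial measurements of quantitative traits, and compound-concentration
(chemotype) profiles. The motivating use case is a medicinal-plant breeding
panel — two dozen accessions of kalmegh (*Andrographis paniculata*) drawn
from several agroecological ecotypes — but nothing in the code is specific
to that crop. The package answers three questions: how informative is each
marker, how heritable is each trait, and how do the three data types
partition the panel into genetic groups.

# Marker informativeness

A dominant fingerprint scores each gel band per accession as present (1),
absent (0) or missing. Per primer the package reports:

* **PIC** (polymorphic information content), $1 - \sum_i f_i^2$. Two modes
  are offered because dominant-data conventions differ. In the default
  `normalized_allele` mode the $f_i$ are band-presence counts normalised to
  sum to one across the primer's bands, treating the band set as an allele
  set — this yields one PIC per primer and is bounded by $1 - 1/B$ for $B$
  bands. In `per_band_mean` mode each band contributes
  $1 - p^2 - (1-p)^2$ at presence proportion $p$ and the per-band values
  are averaged (bound 0.5).
* **Rp** (resolving power), $\sum_b I_b$ with band informativeness
  $I_b = 1 - 2\,|0.5 - p|$. The source literature writes $p$ as a *count*
  of individuals, but $I_b$ only lands in $[0, 1]$ for a proportion, so a
  proportion is used. A `signed` variant $I_b = 2p$ is provided because
  some published tables contain Rp values above the absolute-mode bound
  ($B$), which only arise when the absolute value is dropped; the variant
  exists to reproduce such tables and is never a default.
* **EMR** (effective multiplex ratio), $\mathrm{npb} \cdot
  \mathrm{npb}/\mathrm{tnb}$, with a band called polymorphic iff its
  presence proportion lies strictly between 0 and 1.
* **MI** = EMR × PIC, and **EMI** = MI × DC × QM × PR, where DC = 0.75 and
  PR = 1.0 are the standard documentation-capability and reproducibility
  constants for SSR bands, and QM ∈ [0.25, 1] scores band quality (1.0 for
  single clear bands). The product DC·QM·PR is reported as QND.

All identities (MI = EMR·PIC, EMI = MI·QND) hold at full precision
internally; tables are rounded only for display, which is why a published
MI can differ from the product of its *printed* PIC and EMR by up to about
0.002.

Missing scores follow the `drop_pairwise` policy by default: a band with
any missing value is excluded from that primer's statistics, and similarity
computations use pairwise-complete bands per accession pair. Real gels have
dropouts; silently reading a dropout as "band absent" would bias every
frequency, so missingness is always explicit.

# RCBD variability parameters

Traits come from a randomized complete block design,
$Y_{ij} = \mu + g_i + b_j + e_{ij}$. The ANOVA is the standard two-way
partition (via `stats::aov`); unbalanced layouts are rejected rather than
approximated so the moment estimators stay exact. Components are
$\hat\sigma^2_e = MS_e$ and
$\hat\sigma^2_g = (MS_g - MS_e)/r$ for $r$ blocks, truncated at zero with a
warning. Derived parameters: GCV and PCV
($100\sqrt{\sigma^2}/\bar{y}$ on the genotypic and phenotypic components),
broad-sense heritability $h^2 = \sigma^2_g/\sigma^2_p$ on a **plot basis**
($\sigma^2_p = \sigma^2_g + MS_e$; the cited estimators use this basis and
the alternative mean-basis is not offered), genetic advance
$GA = k\,h^2\sqrt{\sigma^2_p}$ and GA as percent of the mean. The selection
differential defaults to $k = 2.06$ (5% selection intensity), the field's
standard convention. GA is reported both in trait units and as percent of
the mean, since published ranges are often ambiguous between the two.

Multi-year data are expected to be pooled (cell means over years) before
entering the ANOVA; a genotype×year term is out of scope.

# Distances

* **Jaccard similarity** on binary bands: $s = a/(a+b+c)$ over
  pairwise-complete bands; distance is $1 - s$. A pair sharing no scored
  presence has undefined similarity and is an error, not a silent zero.
* **Band-mismatch distance**: $d^2$ = number of differing bands, the
  conventional squared molecular distance for binary data; AMOVA consumes
  the squared values.
* **Standardized Euclidean distance** for trait and chemotype profiles:
  each column is centred and scaled to unit variance before `dist`. The
  scaling uses the *population* variance (denominator $n$): the resulting
  distances are identical under either variance convention up to a global
  factor, but fixing one convention makes files reproducible bit-for-bit;
  the choice is recorded in the run manifest.
* **Fusion** for the joint analysis: each input matrix is divided by its
  maximum off-diagonal entry (range-normalisation to [0, 1]) and the
  normalised matrices are averaged with user weights. The source analyses
  that combine phenotypic and genotypic matrices do not state their
  normalisation; range-normalisation was chosen because it puts
  heterogeneous matrices (band mismatches vs. standardized trait space) on
  a common scale without distorting their rank structure. Equal weights are
  the pipeline default.

# Clustering conventions

The agglomeration (UPGMA, complete, Ward) is written out explicitly rather
than delegated to `hclust`, for two reasons that are conventions, not
algorithms: ties between candidate merges are broken toward the
lexicographically smallest pair of cluster representative labels (stock
implementations leave tie order unspecified, which makes dendrograms
irreproducible across platforms), and the UPGMA merge height is **half**
the between-cluster average distance. With that height convention the
cophenetic distance — defined as twice the lowest-common-ancestor height —
equals the between-cluster average distance on the original scale, so
`copheneticDistance(upgma(D))` returns `D` exactly when `D` is ultrametric.
Tests verify equivalence with `stats::hclust` and with a naive
recompute-from-scratch oracle on random instances, where ties have
probability zero. Newick branch lengths are parent height minus child
height, so trees round-trip losslessly.

Tree cuts use the standard between-merge cut; tied merge heights can make a
requested $k$ unattainable, in which case the nearest attainable partition
is returned with a warning. Dendrogram comparison reports the Pearson
correlation of cophenetic matrices plus, per cut level, the adjusted Rand
index and the number of accessions whose pairwise co-membership differs.

k-means uses Lloyd's algorithm with 25 random restarts per candidate $k$
from a single seeded RNG stream, selecting the $k$ with maximal mean
silhouette width. A maximum below 0.25 is flagged as unsupported structure.
That threshold discriminates noise from structure reliably at a couple of
hundred observations; at panel sizes around 24 the silhouette of pure noise
frequently exceeds 0.25, so for small panels the flag is advisory and the
silhouette curve itself should be inspected. For trait heatmap-style
clustering the linkage is not dictated by the sources; complete linkage is
the default for trait/chemotype trees (configurable), UPGMA for marker
trees.

PCA is the correlation-matrix eigendecomposition (`prcomp`, scaled);
component signs are fixed by making each component's largest-magnitude
loading positive, so outputs are deterministic.

# AMOVA, PCoA, Mantel, delta-K

The one-level AMOVA partitions squared distances among and within
populations: $SS_{tot} = \sum_{i<j} d^2_{ij}/N$,
$SS_{within} = \sum_p \sum_{i<j \in p} d^2_{ij}/n_p$, among by subtraction;
$\sigma^2_w = MS_w$, $\sigma^2_a = (MS_a - MS_w)/n_0$ with
$n_0 = (N - \sum n_p^2/N)/(P-1)$, and
$\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. Two numerical points:
the *reported* $\Phi_{ST}$ and variance percentages truncate a negative
among-component at zero (flagged), but the *permutation test* compares the
untruncated statistic — truncating first would pile half the null
distribution at $\Phi_{ST} = 0$ and make p-values cluster at 1 instead of
being uniform. P-values use the add-one rule $(b+1)/(m+1)$ with 999
permutations by default (the permutation count is not stated in the
motivating analyses; 999 is standard practice). The default distance is the
band-mismatch distance (the convention of the binary-data AMOVA in common
toolkits); a Jaccard-derived distance can be supplied instead — which of
the two the original toolchain used is not documented, so both are
supported and the default is stated here.

PCoA double-centres $-d^2/2$ (Gower) and reports eigenvector coordinates
scaled by $\sqrt{\lambda}$. Negative eigenvalues (non-Euclidean input) are
reported but excluded from the percent-variance denominator; published
cumulative percentages imply a same-sign denominator but do not state the
treatment of negative eigenvalues, so the positive-only convention is
fixed here. The Mantel test correlates upper triangles with simultaneous
row/column permutation, two-sided, add-one rule.

Evanno's method post-processes admixture log-likelihood tables
$L(K)$ over replicate runs: $L'(K)$ is the first difference of means,
$|L''(K)|$ the absolute second difference, and
$\Delta K = |L''(K)| / \mathrm{sd}(L(K))$, defined for interior $K$ with
positive sd. $\Delta K$ is invariant to shifting or rescaling all
log-likelihoods. Running the admixture MCMC itself is out of scope; only
its summary table is consumed.

# The synthetic-data generators

Every statistical claim in the test suite is validated against data with
known truth, generated in code:

* **Markers**: a Balding–Nichols island model. Per locus
  $p_0 \sim U(0.1, 0.9)$, per population
  $p \sim \mathrm{Beta}(p_0\frac{1-F}{F}, (1-p_0)\frac{1-F}{F})$ at
  differentiation $F$, bands Bernoulli. For a binary indicator this model
  gives between-population variance $p_0(1-p_0)F$ and within
  $p_0(1-p_0)(1-F)$, so the AMOVA $\Phi_{ST}$ estimand equals $F$ — which
  is what the recovery tests exploit (at $F = 0.20$, 6 populations of 10
  and 200 loci, the estimate lands within ±0.05). Primers carry two bands;
  by default the second band is the complement of the first
  ("codominant banding", matching panels where every primer shows exactly
  two mutually exclusive polymorphic bands), optionally independent.
* **Traits**: $Y = \mu + g + b + e$ with Normal effects at specified
  variances — exactly the model the RCBD estimators assume.
* **Chemotypes**: Gaussian draws around planted cluster means.

The study-shaped bundle (`makeStudyFixture()`) mirrors the motivating
panel's dimensions: 24 accessions in 6 ecotype populations, 13 two-band
primers, 9 traits (DFF, DM, PH, NNP, NSBP, LL, LW, IL, DHY) in 3 blocks, 4
diterpene compounds (AG, NAG, DDAG, AN in % dry weight), and a
log-likelihood table for $K = 1..10$ × 3 runs with a planted optimum at
$K = 2$. The ecotype sizes (8, 5, 4, 3, 2, 2) are a fixed synthetic choice
— the panel the package emulates had unequal ecotype sizes but their exact
values are not published. Marker differentiation is set at $F = 0.07$,
matching the low among-ecotype share reported for such panels; per-trait
variance components span low to high heritability. These are *generator*
choices: passing tests demonstrate that the estimators recover what the
generator planted, not that any real panel has these values.

What the generators do **not** emulate: linkage between loci, genotype ×
environment interaction, year effects, non-Gaussian trait errors,
compositional constraints among compounds, and missing-data patterns.
Conclusions about robustness to those features cannot be drawn from the
test suite.

# Problem sizes and determinism

Statistical tests run at sizes chosen to make their expectations sharp but
cheap: AMOVA oracle checks at $n \le 12$; $\Phi_{ST}$ recovery at 60
accessions × 200 loci; permutation-p uniformity from 500 random-label
draws at 199 permutations each; heritability recovery from 200 simulated
trials of 100 genotypes × 3 blocks; UPGMA oracle equivalence on 200 random
instances of up to 10 leaves. The full pipeline on the study-shaped bundle
completes in a few seconds. Every stochastic operation takes an explicit
seed and is reproducible bit-for-bit; the pipeline manifest records the
seed, configuration, output paths and md5 digests of every artifact.

# Known limitations

* Co-dominant allele-size data are out of scope (no heterozygosity, no
  allele-frequency AMOVA); only binary band scores are modelled.
* The RCBD machinery requires balance; mixed-model/REML estimation for
  unbalanced trials is deliberately not provided.
* One-level AMOVA only — no region/population hierarchy.
* The silhouette-support threshold is unreliable below ~50 observations
  (see above).
* Graphics are out of scope: the outputs are tables, trees and matrices
  that plotting tools consume.
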