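---
title: "Statistical methods behind screenRRA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind screenRRA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenRRA)
```

`screenRRA` scores selection in pooled CRISPR/Cas9 knockout screens.
This vignette explains the statistical model at each stage, the
parameters a user may want to change, the numerical conventions the
implementation fixes, and what the synthetic-screen tests do and do not
establish about behavior on real data.

## The data and its two key nuisances

The input is an sgRNA-by-sample matrix of sequencing read counts plus
an sgRNA-to-gene map. Two properties of such data drive the design:

* **Unequal sequencing depth.** Library sizes differ by sample, so raw
  counts are not comparable across columns.
* **Overdispersion with few replicates.** Screens typically have two
  (sometimes one) replicates per condition, far too few to estimate a
  per-sgRNA variance, and replicate variances systematically exceed
  Poisson.

## Normalization

Size factors use the median-ratio construction: each sample's factor is
the median over sgRNAs of the count divided by the sgRNA's geometric
mean across samples. The median makes the factor insensitive to the
minority of truly selected sgRNAs, under the assumption that *most
sgRNAs do not change* — the same assumption underlying differential
expression normalization. Conventions fixed here:

* sgRNAs with a zero in any sample are excluded from the median (a
  single zero annihilates the geometric mean) but are still scaled.
* The median of an even-length vector is the mean of the two central
  values.
* Normalized counts are re-rounded to integers, half away from zero
  (`round()`'s half-to-even would make results depend on integer
  parity), and rounding happens once, before any downstream statistic.
  All condition means are therefore means of integer counts.
* If no sgRNA has all-positive counts the median is undefined;
  `total_count_normalize()` (scale to the mean library size) is the
  documented fallback.

## The mean-variance model

Within a condition, the sample mean and variance of each sgRNA are
assumed to follow

$$\sigma^2 = \mu + k\,\mu^b, \qquad k \ge 0,\ b \ge 0,$$

a Poisson term plus a power-law overdispersion term. $(k, b)$ are
estimated by unweighted ordinary least squares of
$\log(\hat\sigma^2 - \hat\mu)$ on $\log\hat\mu$. Points with
$\hat\mu = 0$ or $\hat\sigma^2 \le \hat\mu$ have no defined log and are
excluded; their count is reported in the fitted object. We use the
unbiased ($n-1$) variance estimator. Weighted or trimmed regression was
considered and rejected: with thousands of sgRNAs the fit is already
dominated by the bulk of the cloud, and an unweighted fit keeps the
estimator transparent and easily cross-checked.

A fitted $(\mu, \sigma^2)$ converts to negative binomial parameters by
the method of moments, $p = 1 - \mu/\sigma^2$,
$r = \mu^2/(\sigma^2-\mu)$, with real-valued $r$ (gamma-extended NB).
In `stats::pnbinom()` terms, `size` $= r$ and `prob` $= 1 - p$, so the
NB mean $r\,p/(1-p)$ equals $\mu$ and the variance equals $\sigma^2$.

**Estimator behavior at two replicates.** With two replicates each
$\hat\sigma^2$ has one degree of freedom, and conditioning on
$\hat\sigma^2 > \hat\mu$ selects upward-fluctuating variances. This
biases $k$ upward and attenuates $b$; the effect shrinks quickly with
replicate number. The test suite quantifies this directly: on
10,000-sgRNA screens generated with $k = 0.2, b = 1.5$, the exponent is
recovered within $\pm 0.2$ at two replicates, and both parameters are
recovered closely at eight replicates. Users should read $(k, b)$ from
two-replicate screens as a variance-prediction device, not as unbiased
physical constants. Crucially, the *predicted variances* remain
calibrated: the null sgRNA p-values on two-replicate screens are
uniform to a Kolmogorov–Smirnov distance below 0.05 in the suite.

## The sgRNA test

The control mean $\mu_{iA}$ and model variance
$\sigma^2_{iA} = \mu_{iA} + k\mu_{iA}^b$ define the null NB; two
one-sided tail probabilities against the treatment mean $\mu_{iB}$
score the two selection directions:
$P(X > \mu_{iB})$ for enrichment, $P(X < \mu_{iB})$ for depletion.
Treating the replicate mean $\mu_{iB}$ as the test point against a
single-replicate null distribution is roughly calibrated for 2-vs-2
designs because
$\mathrm{Var}(\hat\mu_{iB} - \hat\mu_{iA}) =
 \sigma^2/2 + \sigma^2/2 = \sigma^2$:
the noise in the estimated control mean and the averaging of the
treatment replicates offset. The null-calibration tests confirm this
at the default design. Numerical conventions:

* Strict inequalities at non-integral thresholds are read literally:
  $x > t$ means integer $x \ge \lfloor t\rfloor + 1$ and $x < t$ means
  $x \le \lceil t\rceil - 1$.
* A zero control mean is replaced by a pseudo-mean of 0.5 normalized
  counts (the NB is undefined at mean zero).
* If the model yields $\sigma^2 \le \mu$ numerically, the variance is
  inflated to $\mu(1 + 10^{-2})$, the documented minimal
  overdispersion.
* p-values are floored at $10^{-300}$ to stay strictly positive.
* sgRNAs with zero counts in *every* sample carry no directional
  evidence; they receive p-values of 1 and always rank last. They are
  retained in the list length $M$ because removing them would shift
  every rank percentile $u_i = r_i/M$.
* Unreplicated controls: moments are pooled over all samples of both
  conditions. This overestimates the null variance whenever true
  selection is present, so single-replicate analyses are conservative.
* Ranking is a total order: p-value, then larger
  $|\mu_{iB} - \mu_{iA}|$, then sgRNA id.

## Gene and pathway aggregation (α-RRA)

Under the null a gene's sgRNA rank percentiles behave like $n$ i.i.d.
uniforms, whose $k$-th order statistic is Beta$(k, n+1-k)$. Classic
robust rank aggregation scores a gene by the minimum over all $n$ beta
order-statistic p-values; the α-modification restricts the minimum to
the $j$ *good* sgRNAs — directional NB p-value below a threshold
(default 0.05) **and** rank within the top α fraction — so that guides
concentrated mid-list (a real failure mode of uniformity-based scores,
including the KS test) cannot produce a significant gene. A gene with
no good guide scores $\rho = 1$.

Choices that were genuinely open, and how they were settled:

* **Default α.** The realized fraction of sgRNAs passing the p-value
  threshold. This makes the two goodness criteria coincide exactly, so
  a single interpretable knob (`p_threshold`) controls selection; both
  remain independently settable.
* **Permutation scheme.** The null reassigns sgRNAs to genes with gene
  sizes preserved. Implementation stratifies by gene size with one
  shared pool of `num_permutations` draws per distinct size (default
  100 × number of genes), which is distribution-identical to permuting
  labels per gene and lets every gene of a size reuse the same pool.
  Goodness transfers by rank: a drawn rank is good iff it lies in the
  good prefix, which is exact because α-selection always selects a
  rank prefix.
* **Empirical p-value.** The add-one estimator
  $(\#\{\rho_0 \le \rho\} + 1)/(B + 1)$, standard for permutation
  tests; it never returns zero.
* **Ranking key.** Genes are ordered by (permutation p, ρ, gene id).
  Permutation p-values have resolution $1/(B+1)$ and tie at the floor
  for strong hits; ρ is continuous and breaks those ties
  deterministically.
* **FDR.** Benjamini–Hochberg step-up across genes (and separately
  across pathways).

Pathways are tested by the identical machinery one level up: genes play
the role of sgRNAs, percentiles come from the gene ranking, a good gene
has permutation p below the threshold within the top α fraction
(paralleling the sgRNA criterion), and the default permutation count is
100 × the number of testable pathways. Database genes absent from the
screen are dropped; results are provably invariant to them.

## The synthetic-screen generator

`simulate_screen()` generates data with exactly the structure the
method assumes: log-normal baseline abundances (default
`meanlog = log(300)`, `sdlog = 1`, i.e. a typical well-covered library
with most sgRNAs between ~40 and ~2000 reads), NB counts obeying
$\sigma^2 = \mu + k\mu^b$ with defaults $k = 0.2, b = 1.5$ (moderate
overdispersion of the kind replicate screens display), and constant
fold changes (default 4) applied to selected genes' treatment means,
optionally jittered per sgRNA to mimic unequal knockout efficiencies.
The default scale — 500 genes × 4 sgRNAs, 2 + 2 replicates — keeps the
full pipeline including permutations inside seconds while leaving
enough sgRNAs (2000) for distributional tests; the variance-recovery
studies raise this to 10,000 sgRNAs.

What the simulator deliberately does **not** model, and hence what
passing tests cannot certify on real screens: sgRNA-sequence-dependent
efficiency and off-target structure, selection-induced violations of
the "most sgRNAs unchanged" normalization assumption (e.g. dropout of
half the library), PCR jackpotting beyond NB dispersion, correlated
replicates, and unequal sgRNA counts per gene. The tests establish
*internal* correctness and calibration — exact oracles for every
closed-form component, uniform null p-values, no false gene calls on
null screens, and recovery of strong spiked effects — not performance
on any particular biological dataset.

## Known limitations

* Two-replicate $(k, b)$ estimates are biased as described above,
  although variance prediction stays calibrated.
* The permutation p-value floor $1/(B+1)$ ties all very strong genes;
  ρ breaks the ties, but FDR values at the floor are resolution-limited.
* Overlapping pathways are tested independently, with no correction
  for shared genes.
* Paired designs, two-sided tests, and fold-change shrinkage are out
  of scope.
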