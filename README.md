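# screenRRA

Selection analysis for genome-scale pooled CRISPR/Cas9 knockout screens.

In a pooled knockout screen, a lentiviral library of single-guide RNAs
(sgRNAs) is delivered to a cell population and each sgRNA's abundance is
read out by sequencing before and after selection. Guides targeting
essential genes drop out of the population (negative selection); guides
knocking out genes that confer resistance to a treatment expand
(positive selection). `screenRRA` takes a table of sgRNA read counts and
identifies the significantly selected sgRNAs, genes, and pathways in
both directions.

## Method

The pipeline has four stages:

1. **Median-ratio normalization.** Counts `x_ij` are scaled by
   per-sample size factors
   `s_j = median_i( x_ij / x̂_i )`, where `x̂_i = (∏_k x_ik)^(1/N)` is
   the geometric mean of sgRNA *i* across samples, then rounded back to
   integers. sgRNAs with a zero count anywhere are excluded from the
   median but still normalized.

2. **Mean-variance modeling.** Replicate counts are overdispersed, so
   per-sgRNA variances are borrowed across sgRNAs through the empirical
   law `σ² = μ + k·μ^b` (k, b ≥ 0), fitted by ordinary least squares of
   `log(σ̂² − μ̂)` on `log(μ̂)` over the sgRNAs whose sample variance
   exceeds their mean. `(μ, σ²)` pairs convert to a (gamma-extended)
   negative binomial by the method of moments:
   `p = 1 − μ/σ²`, `r = μ²/(σ² − μ)`.

3. **sgRNA test.** For each sgRNA the control mean `μ_iA` and
   model-adjusted variance `σ²_iA` define a null NB distribution; two
   one-sided tail probabilities against the treatment mean `μ_iB` —
   `P(X > μ_iB)` and `P(X < μ_iB)` — score positive and negative
   selection. sgRNAs are ranked by p-value in each direction.

4. **α-RRA gene and pathway ranking.** A gene's sgRNA ranks are
   converted to percentiles `u_i = r_i/M`; the k-th smallest percentile
   of *n* uniforms follows Beta(k, n+1−k), giving order-statistic
   p-values `p_k`. The score `ρ = min(p_1 … p_j)` is restricted to the
   *j* "good" sgRNAs — those below an NB p-value threshold (default
   0.05) and within the top α fraction of the list — so that inert
   guides cannot dilute the signal. Significance comes from a
   permutation null (sgRNAs reassigned to genes, gene sizes preserved;
   100 × n_genes draws by default) and Benjamini–Hochberg FDR across
   genes. Pathways are scored identically, with genes playing the role
   of sgRNAs over gene sets from a GMT file.

## Worked example

Simulate a compact screen (500 genes × 4 sgRNAs, 2 control + 2
treatment replicates, 20 genes depleted four-fold) and analyze it:

```r
library(screenRRA)

sim <- simulate_screen(sim_config(n_genes = 500, fraction_neg = 0.04,
                                  effect_size = 4, seed = 1))
design <- design_spec(c("control_1", "control_2"),
                      c("treatment_1", "treatment_2"))
res <- run_screen(sim$table, design, alpha_config(seed = 1),
                  direction = "both")

res$model
#> mean-variance model: sigma^2 = mu + 0.4212 * mu^1.333
#>   fitted on 1249 sgRNAs (751 dropped), log-space R^2 = 0.479

head(res$gene_summary[, c("gene", "n", "j_neg", "rho_neg",
                          "p_neg", "fdr_neg", "rank_neg")], 5)
#>        gene n j_neg      rho_neg       p_neg    fdr_neg rank_neg
#> 1 gene_0418 4     4 1.049760e-07 1.99996e-05 0.00049999        1
#> 2 gene_0213 4     4 3.049801e-07 1.99996e-05 0.00049999        2
#> 3 gene_0079 4     4 3.603001e-07 1.99996e-05 0.00049999        3
#> 4 gene_0129 4     4 4.569760e-07 1.99996e-05 0.00049999        4
#> 5 gene_0438 4     4 4.931551e-07 1.99996e-05 0.00049999        5
```

All five top-ranked genes are truly depleted (`sim$truth`). Reading the
columns: `n` is the number of sgRNAs targeting the gene, `j_neg` how
many of them were α-selected as significantly depleted, `rho_neg` the
min-of-beta order-statistic score over those guides, `p_neg` the
permutation p-value (its floor, `1/(100·500 + 1) ≈ 2.0e-05`, means the
observed ρ beat every null draw), `fdr_neg` the Benjamini–Hochberg
q-value, and `rank_neg` the gene's position in the depletion ranking.

Real screens are analyzed the same way from a tab-delimited count file
(columns: sgRNA, gene, one column per sample) with
`read_count_table()`, optionally adding `gmt = "pathways.gmt"` for
pathway-level results. A command-line wrapper with `test`, `pathway`
and `simulate` subcommands is installed at
`system.file("scripts", "screenrra", package = "screenRRA")`.

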