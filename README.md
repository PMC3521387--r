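# epicontrast

Prioritization of candidate epistatic SNP pairs in case/control GWAS data by
**case/control correlation contrast**.

## The problem and the statistic

Exhaustive pairwise interaction scans face two obstacles: scale (a
500,000-SNP panel has ≈1.25 × 10¹¹ pairs) and confounded dependence —
linkage disequilibrium, population structure and assay artifacts make SNP
pairs look dependent for reasons that have nothing to do with disease.
`epicontrast` addresses the second problem by measuring genotype dependence
*separately* within cases and within controls and ranking pairs by the
disagreement between the two groups.

Genotypes are encoded x ∈ {−1, 0, +1} for homozygous wild / heterozygous /
homozygous variant. For a SNP pair within one phenotype group, with P the
3 × 3 joint genotype probability table,

    ρ = (P_ww − P_wv − P_vw + P_vv) / sqrt( (P_x=w + P_x=v) · (P_y=w + P_y=v) )
      = E[xy] / sqrt( E[x²] · E[y²] )        (second-moment ratio, ρ ∈ [−1, 1])

and every pair is scored by the contrast

    ρ_diff = | ρ_control − ρ_case |  ∈ [0, 2].

Dependence shared by both groups (LD, stratification) cancels in ρ_diff;
disease-specific co-segregation survives. Pairs are ranked by ρ_diff — the
heavy-tailed score distribution makes fixed P-value cutoffs inappropriate —
and the top-K list carries Weibull(k = 1, λ = 0.018) upper-tail P-values for
orientation, plus a hub-SNP summary. The package also ships a
penetrance-model simulator (Hardy–Weinberg sampling, rejection to exact
case/control quotas, single-table and interaction-network models) and an
evaluation harness with scenario-specific accuracy rules and ROC curves.

## Worked example

Simulate a strong two-locus epistatic panel (MAF 0.2, 800 cases + 800
controls, 100 SNPs), scan all 4950 pairs, and rank:

```r
library(epicontrast)

model  <- read_model_spec(example_model_path("strong_2locus"))
sim    <- simulate_dataset(model, n_case = 800, n_control = 800,
                           n_snps = 100, seed = 7)
scores <- scan_pairs(sim$genotypes, sim$phenotypes)
glance(scores)
#> # A tibble: 1 × 6
#>   n_snps n_pairs n_valid n_case n_control max_rho_diff
#>    <int>   <int>   <int>  <int>     <int>        <dbl>
#> 1    100    4950    4950    800       800        0.513

ranked <- rank_pairs(scores, k = 10)
head(tidy(ranked)[, c("rank", "snp_i", "snp_j", "rho_case",
                      "rho_control", "rho_diff", "p_value")], 3)
#>    rank snp_i   snp_j   rho_case rho_control rho_diff  p_value
#> 1     1 snp0034 snp0067    0.939       0.427    0.513 4.28e-13
#> 2     2 snp0034 snp0100    0.822       0.527    0.296 7.26e- 8
#> 3     3 snp0034 snp0094    0.819       0.564    0.255 7.11e- 7

sim$truth$true_pairs     # the planted interacting pair
#>       i     j
#> 1    34    67
```

The planted pair (SNPs 34 and 67) is rank 1 with ρ_diff = 0.513
(P ≈ 4.3 × 10⁻¹³): in cases the two loci co-segregate strongly
(ρ_case = 0.94) while controls sit near the independence baseline. Note the
baseline itself is positive — the second-moment ratio is not mean-centered,
so independent loci with MAF < 0.5 share a positive ρ in *both* groups; it
cancels in the contrast. `detect_hubs(ranked)` tallies SNPs recurring across
top pairs (here snp0034, degree 9 of 10), and `summarize_topk(ranked)` /
`glance(ranked)` report the 1st and K-th scores, their P-values, and the
mean ± SD over the list.

Tail P-values reproduce the published Weibull lookup behavior exactly,
including the double-precision quantization at extreme scores:

```r
weibull_tail_pvalue(c(0.05, 0.30, 0.65))
#> [1] 6.217652e-02 5.777749e-08 2.220446e-16
```

A thin command-line wrapper over the same functions lives at
`inst/cli/epicontrast.R` (subcommands `simulate`, `scan`, `rank`,
`evaluate`; every run writes a JSON manifest for reproducibility).

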