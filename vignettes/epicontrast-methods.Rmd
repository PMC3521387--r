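---
title: "Case/control correlation contrast for epistasis screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/control correlation contrast for epistasis screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicontrast)
library(dplyr)
```

## The problem

Genome-wide association studies test SNPs one at a time, but part of the
genetic architecture of complex disease is expected to be epistatic: the
effect of one locus depends on the genotype at another. Screening all SNP
pairs for interaction is combinatorially heavy — a 500,000-SNP panel has
about 1.25 × 10^11 pairs — and the dominant source of pairwise dependence in
genotype data is not disease at all but linkage disequilibrium (LD),
population structure, and assay artifacts, which affect cases and controls
alike.

`epicontrast` screens pairs with a statistic built around that observation:
measure genotype dependence *within each phenotype group separately* and
rank pairs by how much the two groups disagree. Dependence shared by both
groups cancels; dependence specific to disease status survives.

## The statistic

Each biallelic SNP genotype is coded homozygous wild (w), heterozygous (h),
homozygous variant (v) and encoded numerically as x ∈ {−1, 0, +1}. For a
SNP pair (x, y) within one group, let P be the 3 × 3 joint genotype
probability table estimated by cell counts over the group's individuals.
The dependence score is

$$
\rho \;=\; \frac{P_{ww} - P_{wv} - P_{vw} + P_{vv}}
     {\sqrt{(P_{x=w}+P_{x=v})\,(P_{y=w}+P_{y=v})}}
\;=\; \frac{E[xy]}{\sqrt{E[x^2]\,E[y^2]}},
$$

a second-moment ratio of the encoded variables. Heterozygotes contribute 0
to every moment, so ρ is driven by the co-occurrence pattern of homozygote
classes; it lies in [−1, 1] by Cauchy–Schwarz and tracks haplotype-level LD
monotonically (a property the test suite checks by simulating genotype
pairs from haplotypes with known r).

Two remarks on this form. First, it is a ratio of *raw* second moments, not
a mean-centered Pearson correlation; the two coincide only when the encoded
genotype means are zero. We implement the closed form above verbatim — no
mean-centering is added — because the closed form is the defined statistic,
and all downstream calibration refers to it. Second, ρ is undefined in a
group where a SNP has no homozygotes at all (a marginal factor is zero);
such pairs are flagged invalid and excluded from ranking rather than scored
0, since any finite placeholder would distort the ranking.

Each pair gets ρ_case and ρ_control, and the ranking score is the contrast

$$\rho_{\mathrm{diff}} = |\rho_{\mathrm{control}} - \rho_{\mathrm{case}}| \in [0, 2].$$

Under an allele relabel (w ↔ v) at one SNP, both group ρ values flip sign
together and ρ_diff is unchanged, which is why the package can adopt an
arbitrary but deterministic allele-orientation convention (major allele in
the pooled sample = wild; lexicographic tie-break) without affecting
results.

## Ranking and tail P-values

Pairs are ranked by decreasing ρ_diff with ties broken by pair index, and
the top K (default 1000) are reported. Ranking, not a significance cutoff,
is the selection interface: the empirical genome-wide ρ_diff distribution
is heavy-tailed, and a fixed P-value cutoff admits enormous numbers of
pairs while Bonferroni-style corrections presume independence the pairs do
not have.

For orientation, each reported pair still carries an upper-tail probability
from a Weibull distribution with shape k = 1 and scale λ = 0.018, the shape
that describes the genome-wide empirical ρ_diff distribution. The default
evaluation computes `1 - pweibull(score, k, λ)` in double precision. Near
the top of the distribution the CDF is within a few machine epsilons of 1,
so the complement is quantized to multiples of 2.2204 × 10^−16 and
underflows to exactly 0 for scores above ~0.69: this reproduces the
published lookup table bit for bit, which is the package's regression
anchor. `exact = TRUE` instead evaluates exp(−(s/λ)^k) directly and should
be preferred when the magnitude of a very small tail probability matters:

```{r weibull}
tibble(score = c(0.05, 0.30, 0.65, 0.70),
       default = weibull_tail_pvalue(score),
       exact   = weibull_tail_pvalue(score, exact = TRUE))
```

Hub SNPs — markers recurring across many top pairs — are tallied by
`detect_hubs()`; degrees sum to 2K by construction.

## The simulator

`simulate_dataset()` generates case/control panels from explicit penetrance
models, the structure used throughout the epistasis-benchmark literature:

* every locus is sampled under Hardy–Weinberg equilibrium from its
  variant-allele frequency q, genotype probabilities ((1−q)², 2q(1−q), q²);
* background SNP frequencies are drawn once, uniformly on (0.05, 0.5) by
  default — consistent with the MAF > 0.05 regime in which the statistic is
  normally applied;
* disease status is Bernoulli with probability given by the model's
  penetrance at the individual's disease-locus genotypes;
* rejection sampling continues until exactly `n_case` and `n_control`
  individuals are accumulated, with a draw budget (default 10^8) guarding
  against pathological models. The rejection stream's totals are returned
  as diagnostics, so the realized prevalence can be compared with the
  analytic value Σ HWE(g)·pen(g) from `analytic_prevalence()`.

Disease loci are embedded at fixed, evenly spaced panel positions by
default: position carries no information for the statistic and fixed
placement keeps truth bookkeeping trivial.

Higher-order architectures are expressed as interaction networks: loci as
nodes, two-locus penetrance tables as edges. Edges combine under the
heterogeneity rule, pen = 1 − Π(1 − pen_edge), treating each interacting
pair as an independent disease route — the standard composition in the
multi-locus simulation literature; a multiplicative rule (product rescaled
by its maximum) is offered as an alternative. How published network
benchmarks combined their pairwise tables is not always documented, so the
composition rule is a configuration choice here, with heterogeneity as the
default.

The shipped model files under `inst/extdata/models/` are reconstructions
written for this package (marked as such in their headers), not copies of
any published supplement: `strong_2locus` raises risk (0.25 vs 0.02
baseline) when the two loci carry the *same* homozygous genotype at
MAF 0.2 — a high-contrast pattern chosen so that cases show strong positive
genotype correlation while controls show none; `marginal_2locus` is a
multiplicative model whose single loci are also associated;
`null_2locus` is constant penetrance 0.5 (no genotype–disease association);
`network_4locus_het` joins two disjoint strong edges (0.35 vs 0.01) under
heterogeneity.

What the simulator deliberately does **not** model: LD between background
SNPs, population structure, genotyping error, and missingness. Passing
tests on simulated panels therefore demonstrate the statistic's behavior
under clean HWE sampling with independent markers, not robustness to the
correlated background of real genotype data — on real data the contrast
relies on LD affecting cases and controls equally, which stratified or
differentially genotyped cohorts can violate.

## Evaluation rules

The evaluation harness scores a ranking against simulation truth with
scenario-specific rules: a single interacting pair is detected only if it
is *the* rank-1 pair; for five independent pairs, all ten disease SNPs must
appear within the top five pairs; for interaction networks, the maximal
prefix of the ranking in which every pair contains at least one disease SNP
must jointly cover all disease SNPs. The network rule's phrase "consecutive
top pairs" admits more than one reading; we formalize it as that maximal
prefix — the strictest reading consistent with "consecutive" — and note
that pairs linking a disease SNP to a background SNP extend the prefix
without helping coverage. ROC curves sweep sensitivity/specificity over the
exact set of observed ρ_diff values (plus ∞ for the empty-call corner); at
desk scale there is no reason to coarsen to a fixed grid. True positives
are the truly interacting pairs only; a pair joining one disease SNP to a
background SNP counts as a negative.

## Numerical and design choices

* **Missing genotypes** are kept as a −9 sentinel and handled pairwise
  complete-case, per pair and per group: each pair uses every individual
  observed at both its SNPs. This is the least-assumption choice and keeps
  every pair's n as large as the data allow.
* **Multiallelic markers are rejected**, not recoded: the 3 × 3 table is
  biallelic by construction.
* **Coordinates** are 0-based half-open internally; BED input is native and
  .map positions are shifted on read. Gene-region filtering expands each
  interval by a flank (default 10 kb) on both sides, clipped at zero.
* **MAF filtering** uses a strict inequality (MAF > threshold) over pooled
  non-missing genotypes.
* **Chunked scanning**: the pair matrix is processed in blocks
  (default 10,000 SNPs) and each block pair is tallied with dense
  integer-indicator matrix products, so any chunk size — and any nominal
  worker count — yields bit-identical scores; output is sorted by (i, j).
  All probabilities and scores are double precision throughout.
* **Determinism**: every simulation is reproducible from a single integer
  seed, and pipeline runs write a JSON manifest of command, parameters and
  seed alongside their outputs.

## Problem sizes in the shipped checks

The test-suite and acceptance-script simulations use the validation-study
conditions — 100-SNP panels with 800 + 800 samples for two-locus models and
400 + 400 for the four-locus network, 100 seeded replicates per scenario —
plus a 50,000-draw calibration run for prevalence; pair-count arithmetic for
genome-scale panels (355,882 and 500,000 SNPs) is checked as arithmetic,
without executing a genome-scale scan. These sizes exercise every code path
at full statistical fidelity.

## Known limitations

* Only binary case/control phenotypes are supported; the contrast is
  defined on exactly two groups.
* ρ is blind to dependence expressed purely through heterozygotes (both
  encodings 0), and undefined where a group lacks homozygotes at a SNP;
  such pairs are reported invalid rather than imputed.
* The Weibull parameters are configuration with published defaults, not
  refit to the data at hand; for a panel whose ρ_diff distribution departs
  from that shape, the attached P-values are orientation only. The ranking
  itself never depends on them.
* No haplotype phasing, covariate adjustment, or >2-locus joint statistics:
  higher-order architectures are detected through their pairwise contrast
  footprints.
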