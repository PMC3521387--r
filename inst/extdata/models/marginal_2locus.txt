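# Two-locus interaction model with marginal effects (synthetic
# reconstruction). Multiplicative risk in the product of variant-allele
# counts, pen = 0.05 * 1.8^(n1*n2), a common shape for models whose single
# loci also show association. MAF 0.5 at both loci.
type: penetrance
L: 2
mafs: 0.5 0.5
label: marginal_2locus
table:
0.05 0.05 0.05
0.05 0.09 0.162
0.05 0.162 0.52488
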