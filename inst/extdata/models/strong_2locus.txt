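# Strong two-locus epistatic model (synthetic reconstruction).
# Risk is elevated only when both loci carry the same homozygous genotype
# (both wild or both variant), which induces a strong positive genotype
# correlation among cases and none among controls. Representative of the
# high-heritability regime of two-locus benchmark model families; the table
# is a reconstruction written for this package, not a published table.
type: penetrance
L: 2
mafs: 0.2 0.2
label: strong_2locus
h2: 0.4
table:
0.25 0.02 0.02
0.02 0.02 0.02
0.02 0.02 0.25
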