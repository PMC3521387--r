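# Null model: constant penetrance 0.5 regardless of genotype. Disease status
# is independent of all loci; used for calibration and chance-level accuracy
# checks.
type: penetrance
L: 2
mafs: 0.25 0.25
label: null_2locus
table:
0.5 0.5 0.5
0.5 0.5 0.5
0.5 0.5 0.5
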