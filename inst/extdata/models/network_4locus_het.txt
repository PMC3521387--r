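# Four-locus interaction network (synthetic reconstruction): two disjoint
# pairwise interactions A-B and C-D, each a concordant-homozygote table
# (pen 0.35 when both loci are the same homozygote, 0.01 otherwise),
# combined under the heterogeneity rule 1 - prod(1 - pen_edge).
# Edge tables are in odometer order over {w,h,v}^2, first locus slowest.
type: network
combine: heterogeneity
node: A 0.2
node: B 0.2
node: C 0.2
node: D 0.2
edge: A B 0.35 0.01 0.01 0.01 0.01 0.01 0.01 0.01 0.35
edge: C D 0.35 0.01 0.01 0.01 0.01 0.01 0.01 0.01 0.35
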