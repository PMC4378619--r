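# demo configuration: synthetic two-genotype read-through study
seed = 7

[simulation]
n_loci = 12
contig_length = 50000

[extension]
min_coverage = 5
max_gap = 25

[de]
fold_change = 1.5
p_max = 0.05
fdr_max = 0.1
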