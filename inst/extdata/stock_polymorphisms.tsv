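# Polymorphisms detected in the ancestral phage stock (fraction of reads).
# The 86 bp duplication inside gene 57 was never observed in evolved
# isolates; the gene-52 SNV was present in three evolved lineages and is
# therefore treated as pre-existing rather than parallel.
position	bp_change	frequency
28380	C->A	0.304
31648	+86 bp	0.159
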