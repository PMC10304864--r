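# Curated whole-population mutation set for the packaged fixture phage
# genome: long format, one row per (mutation, population), with the
# fraction of sequencing reads supporting the mutation. 100% means no
# other allele was detected at the locus.
position	bp_change	source_id	population	frequency
11048	T->G	Pop+2	Pop+2	6.7%
11048	T->G	Pop+4	Pop+4	7.6%
11048	T->G	Pop+6	Pop+6	6.9%
19245	T->G	Pop+4	Pop+4	9.5%
19261	A->T	Pop+2	Pop+2	5.6%
19261	A->T	Pop+4	Pop+4	5.7%
19261	A->T	Pop+6	Pop+6	5.4%
19272	C->G	Pop+4	Pop+4	5.0%
28296	C->A	Pop+4	Pop+4	100%
28321	C->A	Pop+4	Pop+4	100%
28380	C->A	Pop+4	Pop+4	100%
28380	C->A	Pop+6	Pop+6	100%
28380	C->A	Pop+8	Pop+8	100%
28381	A->G	Pop+2	Pop+2	100%
28383	G->A	Pop+8	Pop+8	100%
28446	C->A	Pop+6	Pop+6	100%
28463	C->G	Pop+2	Pop+2	100%
28463	C->G	Pop+6	Pop+6	100%
28469	C->A	Pop+2	Pop+2	100%
31700	+82 bp	Pop+8	Pop+8	77.2%
31718	+86 bp	Pop+6	Pop+6	63.6%
31917	C->A	Pop+6	Pop+6	100%
31917	C->A	Pop+8	Pop+8	100%
38211	del 1 bp	Pop+4	Pop+4	100%
39132	T->G	Pop+4	Pop+4	5.0%
39132	T->G	Pop+6	Pop+6	5.3%
39139	C->A	Pop+4	Pop+4	6.6%
39139	C->A	Pop+6	Pop+6	6.9%
48412	G->T	Pop+2	Pop+2	5.8%
48412	G->T	Pop+4	Pop+4	5.1%
48412	G->T	Pop+6	Pop+6	5.4%
48438	G->T	Pop+2	Pop+2	8.9%
48438	G->T	Pop+4	Pop+4	8.6%
48438	G->T	Pop+6	Pop+6	8.9%
48444	T->A	Pop+2	Pop+2	6.4%
48444	T->A	Pop+4	Pop+4	5.5%
48444	T->A	Pop+6	Pop+6	5.5%
48446	A->C	Pop+2	Pop+2	10.6%
48446	A->C	Pop+4	Pop+4	9.9%
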