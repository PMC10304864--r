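# Curated isolate mutation set for the packaged fixture phage genome:
# long format, one row per (mutation, isolate) occurrence.
# Isolates are day-10 clones, one per surviving replicate population.
position	bp_change	source_id	population
28296	C->A	RB-022	Pop+4
28321	C->A	RB-022	Pop+4
28380	C->A	RB-022	Pop+4
28380	C->A	RB-028	Pop+8
28380	C->A	ET013	Pop+9
28381	A->G	RB-020	Pop+2
28383	G->A	RB-028	Pop+8
28411	G->T	ET013	Pop+9
28463	C->G	RB-020	Pop+2
28463	C->G	RB-024	Pop+6
28469	C->A	RB-020	Pop+2
28469	C->A	ET013	Pop+9
31917	C->A	RB-024	Pop+6
31917	C->A	RB-028	Pop+8
31917	C->A	ET013	Pop+9
35091	(A)8->7	RB-022	Pop+4
38215	(T)5->4	RB-022	Pop+4
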