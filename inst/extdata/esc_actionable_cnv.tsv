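patient_id	chrom	start	end	gene	n_bins	log2_ratio	call
3	14	105235000	105262000	AKT1	10	1.1	gain
7	7	116312000	116438000	MET	10	1.1	gain
13	3	178865000	178957000	PIK3CA	10	1.1	gain
7	3	178865000	178957000	PIK3CA	10	1.1	gain
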