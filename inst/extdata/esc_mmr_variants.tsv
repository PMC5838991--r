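patient_id	chrom	pos	ref	alt	gene	variant_class	protein_change	cdna_change	vaf	alt_reads	depth	cosmic	popfreq_1000g	popfreq_exac	sift	clinvar_sig
1	2	47630232	G	A	MSH2	missense	p.V78I	c.G232A	0.25	75	300	FALSE			deleterious	
2	12	133250250	C	G	POLE	missense	p.E991Q	c.G2971C	0.25	75	300	FALSE			deleterious	
2	2	190656516	C	T	PMS1	missense	p.A6V	c.C17T	0.25	75	300	FALSE			deleterious	
2	2	47693796	G	A	MSH2	missense	p.A600T	c.G1798A	0.25	75	300	FALSE			deleterious	
3	2	47702183	A	G	MSH2	missense	p.Q629R	c.A1886G	0.25	75	300	FALSE			neutral	Not_provided;benign
3	3	37090508	C	A	MLH1	missense	p.Q701K	c.C2101A	0.25	75	300	FALSE			neutral	Likely_benign;pathogenic
4	2	47710088	C	T	MSH2	stopgain	p.R929X	c.C2785T	0.25	75	300	FALSE				Pathogenic
4	2	47690181	A	G	MSH2	missense	p.T564A	c.A1690G	0.25	75	300	FALSE			neutral	Benign
5	7	6026708	C	G	PMS2	missense	p.H435Q	c.C1305G	0.25	75	300	FALSE			neutral	
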