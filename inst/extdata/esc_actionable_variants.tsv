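patient_id	chrom	pos	ref	alt	gene	variant_class	protein_change	cdna_change	vaf	alt_reads	depth	cosmic	popfreq_1000g	popfreq_exac	sift	clinvar_sig
7	16	3820000	G	A	CREBBP	stopgain	p.Q540X	c.C1618T	0.3	90	300	FALSE				
3	12	121431000	A	AC	HNF1A	frameshift_indel	p.288fs	c.864_865insC	0.3	90	300	FALSE				
8	2	209113112	C	T	IDH1	missense	p.R132H	c.G395A	0.3	90	300	TRUE				
6	17	29576000	T	A	NF1	splice		c.A3975-2T	0.3	90	300	FALSE				
12	3	178936091	G	A	PIK3CA	missense	p.E545K	c.G1633A	0.3	90	300	TRUE				
2	3	178951957	A	G	PIK3CA	missense	p.M1043V	c.A3127G	0.3	90	300	TRUE				
6	10	89692904	AG	A	PTEN	frameshift_indel	p.R142fs	c.425delG	0.3	90	300	FALSE				
13	17	7577580	T	C	TP53	missense	p.Y234C	c.A701G	0.3	90	300	TRUE				
9	17	7577121	G	A	TP53	missense	p.R273C	c.C817T	0.3	90	300	TRUE				
2	17	7578263	G	A	TP53	stopgain	p.R196X	c.C586T	0.3	90	300	TRUE				
7	17	7577022	G	A	TP53	stopgain	p.R306X	c.C916T	0.3	90	300	TRUE				
2	17	7578213	CT	C	TP53	frameshift_indel	p.V218fs	c.652delA	0.3	90	300	FALSE				
5	17	7577545	TC	T	TP53	frameshift_indel	p.N239fs	c.715delG	0.3	90	300	FALSE				
12	17	7578440	GA	G	TP53	frameshift_indel	p.K139fs	c.416delT	0.3	90	300	FALSE				
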