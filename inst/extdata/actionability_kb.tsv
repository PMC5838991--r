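gene	pattern_type	pattern_value	therapy	evidence_note	citation_tag
AKT1	amplification		mTOR inhibitors; AKT inhibitor MK2206	response to mTOR inhibition and MK2206	akt1-amp
CREBBP	exact_protein_change	p.Q540X	HDAC inhibitors	active clinical trial	crebbp-hdac
HNF1A	exact_protein_change	p.288fs	mTOR inhibitors	in-vitro mTOR-inhibitor response	hnf1a-mtor
IDH1	exact_protein_change	p.R132H	IDH1 and pan-IDH inhibitors	active clinical trial	idh1-r132h
MET	amplification		c-MET inhibitors	response to c-MET inhibition	met-amp
NF1	splice_disruption	c.A3975-2T	MEK inhibitors	possibly increased MEK-inhibitor sensitivity	nf1-splice
PIK3CA	exact_protein_change	p.E545K	PI3K/AKT/mTOR inhibitors	activating helical-domain hotspot	pik3ca-e545k
PIK3CA	exact_protein_change	p.M1043V	PI3K/AKT/mTOR inhibitors	activating kinase-domain variant	pik3ca-m1043v
PIK3CA	amplification		PI3K/AKT/mTOR inhibitors	pathway activation by copy gain	pik3ca-amp
PTEN	exact_protein_change	p.R142fs	PI3K/AKT/mTOR inhibitors	PI3K pathway activation by PTEN loss	pten-fs
TP53	exact_protein_change	p.Y234C	bevacizumab; pazopanib	better bevacizumab/pazopanib response	tp53-y234c
TP53	exact_protein_change	p.R273C	bevacizumab; pazopanib	better bevacizumab/pazopanib response	tp53-r273c
TP53	truncation_class	nonsense	bevacizumab; pazopanib	better bevacizumab/pazopanib response	tp53-nonsense
TP53	truncation_class	frameshift	bevacizumab; pazopanib	better bevacizumab/pazopanib response	tp53-frameshift
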