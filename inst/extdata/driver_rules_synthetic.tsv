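gene	cancer_type	role	recurrent_sites
PIK3CA	breast	oncogene	542,545,546,1047
AKT1	breast	oncogene	17
ESR1	breast	oncogene	536,537,538
MYC	breast	oncogene	
ARID1B	breast	tsg	
SPEN	breast	tsg	
GATA3	breast	tsg	
TP53	breast	tsg	
FGFR2	biliary	oncogene	252,549
IDH1	biliary	oncogene	132
BAP1	biliary	tsg	
NSD1	biliary	tsg	
TP53	biliary	tsg	
EGFR	lung	oncogene	790,858
KRAS	lung	oncogene	12,13,61
STK11	lung	tsg	
TP53	lung	tsg	
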