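gene	cancer_type
TP53	breast
PTEN	breast
CDH1	breast
SMAD4	biliary
ARID1A	biliary
KEAP1	lung
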