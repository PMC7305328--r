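cancer_type,total_slides,failed_qc
BLCA,380,14
BRCA,1096,88
CESC,249,54
GBM,772,40
LUAD,540,59
LUSC,431,35
PAAD,190,11
PRAD,387,19
SKCM,470,64
UCEC,545,192
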