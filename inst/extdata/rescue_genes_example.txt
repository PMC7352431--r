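# Illustrative cancer-gene rescue list (synthetic example, not a curated
# census): oncogenes, tumor suppressors and autosomal dominant familial
# syndrome genes handled leniently at the CADD/conservation/vote stages.
POT1
TP53
BRCA1
BRCA2
APC
RET
PTEN
CHEK2
MLH1
MSH2
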