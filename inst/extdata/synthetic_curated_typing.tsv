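component	type
BMP7	L
TGFB1	L
TGFB2	L
ANXA1	L
CXCL1	L
CXCL3	L
CCL3	L
CCL4L2	L
CCL7	L
COL1A1	L
COL4A1	L
LAMB1	L
WNT5A	L
DLL1	L
JAG1	L
ACVR1+ACVR2A	R
TGFBR1+TGFBR2	R
FPR1	R
CXCR1	R
CXCR2	R
CCR1	R
CCR5	R
ITGA1+ITGB1	R
ITGA2+ITGB1	R
NOTCH1	R
FZD5	R
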