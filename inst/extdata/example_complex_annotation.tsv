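protein	complex
KAT7	JADE
JADE1	JADE
JADE2	JADE
MEAF6	JADE
ING4	JADE
ING5	JADE
BRPF3	BRPF
KAT8	MSL
MSL1	MSL
MSL2	MSL
MSL3	MSL
KANSL1	NSL
KANSL2	NSL
KANSL3	NSL
HCFC1	NSL
MCRS1	NSL
OGT	NSL
PHF20	NSL
PHF20L1	NSL
WDR5	NSL
KAT5	NuA4
EPC1	NuA4
EPC2	NuA4
DMAP1	NuA4
ING3	NuA4
MBTD1	NuA4
YEATS4	NuA4
VPS72	NuA4
EP400	NuA4
BRD8	NuA4
RUVBL1	NuA4
RUVBL2	NuA4
MORF4L1	NuA4
TRRAP	NuA4
MORF4L2	NuA4
ACTL6A	NuA4
MRGBP	NuA4
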