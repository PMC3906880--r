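cluster	KM1	KM2	KM3	KM4	KM5	KM6	KM7	KM8
CLMM_WT1	27	0	0	0	10	0	0	0
CLMM_WT2	11	10	14	0	0	6	0	0
CLMM_WT3	13	0	10	0	2	0	0	0
CLMM_WT4	0	0	3	8	0	0	0	0
CLMM_WT5	0	0	6	0	0	32	0	0
CLMM_WT6	0	9	0	0	0	51	0	0
CLMM_WT7	0	0	0	0	0	1	16	0
CLMM_WT8	1	9	0	0	0	7	0	10
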