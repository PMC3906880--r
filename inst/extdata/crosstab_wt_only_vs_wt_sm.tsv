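cluster	Both1	Both2	Both3	Both4	Both5	Both6	Both7	Both8
CLMM_WT1	13	1	3	0	2	0	0	3
CLMM_WT2	21	33	0	0	0	0	0	0
CLMM_WT3	3	0	22	0	0	0	0	1
CLMM_WT4	0	0	0	11	0	0	0	0
CLMM_WT5	0	2	0	0	30	2	0	0
CLMM_WT6	0	1	0	0	4	50	0	0
CLMM_WT7	0	0	0	0	0	0	17	0
CLMM_WT8	0	4	0	0	2	8	0	23
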