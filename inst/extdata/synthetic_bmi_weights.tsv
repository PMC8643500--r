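SNP	EA	OA	EAF	BETA	SE
rs1	A	G	0.42	0.031	0.003
rs2	C	T	0.18	0.025	0.004
rs3	G	A	0.55	0.019	0.003
rs4	T	C	0.31	0.022	0.003
rs5	A	C	0.09	0.040	0.006
rs6	G	T	0.47	0.017	0.003
rs7	C	G	0.26	0.028	0.004
rs8	T	A	0.61	0.021	0.003
rs9	A	G	0.35	0.024	0.003
rs10	C	T	0.52	0.018	0.003
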