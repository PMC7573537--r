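roi	execution	inhibition
L_preSMA	0.24	0.21
L_IFG	0.25	0.19
L_STR	0.66	0.40
L_GPe	7.68	0.20
L_GPi	0.21	0.43
L_SN	0.22	0.40
L_STN	0.63	0.20
L_THAL	20.87	0.31
R_preSMA	599.72	62921.33
R_IFG	87265.65	1454887.67
R_STR	0.89	3369.02
R_GPe	0.21	7.12
R_GPi	0.23	0.24
R_SN	0.56	21.07
R_STN	0.72	31.30
R_THAL	0.34	72.37
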