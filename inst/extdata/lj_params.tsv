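class	epsilon	radius	polar
N_BB	0.2384	1.63	TRUE
CA_BB	0.0486	1.93	FALSE
C_BB	0.141	1.8	FALSE
O_BB	0.1591	1.53	TRUE
C_ALI_CH3	0.1811	1.92	FALSE
C_ALI_CH2	0.1142	1.9	FALSE
C_ALI_CH1	0.0486	1.95	FALSE
C_ARO	0.12	1.85	FALSE
C_AMIDE	0.141	1.8	FALSE
C_CARBOXYL	0.141	1.8	FALSE
C_GUANIDO	0.141	1.8	FALSE
O_AMIDE	0.1591	1.53	TRUE
O_CARBOXYL	0.6469	1.52	TRUE
O_HYDROXYL	0.1591	1.55	TRUE
N_AMIDE	0.2384	1.63	TRUE
N_AMINE	0.2384	1.65	TRUE
N_GUANIDINIUM	0.2384	1.63	TRUE
N_RING	0.2384	1.62	TRUE
S_THIOL	0.043	1.95	FALSE
S_THIOETHER	0.043	1.95	FALSE
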