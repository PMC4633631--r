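disease	h2_auto	se_auto	p_auto	h2_exmhc	se_exmhc	p_exmhc	pct_mhc	h2_x	se_x	p_x
CD	0.454	0.025	1.00e-04	0.447	0.025	1.00e-04	1.54	0.014	0.004	2.35e-04
CEL	0.447	0.362	1.06e-01	0.337	0.361	1.74e-01	24.72	0.048	0.058	1.89e-01
CVID	0.181	0.063	1.72e-03	0.167	0.063	3.66e-03	8.12	NA	NA	NA
EPI	0.168	0.027	1.05e-10	0.163	0.027	3.90e-10	2.91	0.010	0.005	1.21e-02
JIA	0.727	0.037	1.00e-04	0.650	0.037	1.00e-04	10.66	0.027	0.007	4.91e-06
PS	0.949	0.381	5.90e-03	0.949	0.380	5.87e-03	-0.02	0.003	0.061	4.82e-01
SLE	0.206	0.076	3.16e-03	0.202	0.076	3.74e-03	1.89	0.013	0.013	1.60e-01
SPA	0.370	0.192	2.45e-02	0.310	0.191	4.91e-02	16.17	-0.029	0.028	1.74e-01
T1D	0.863	0.070	1.00e-04	0.581	0.069	1.00e-04	32.66	0.028	0.012	5.27e-03
UC	0.386	0.041	1.00e-04	0.363	0.041	1.00e-04	5.84	0.012	0.007	3.38e-02
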