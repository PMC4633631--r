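pair	rg_auto	se_auto	p_auto	rg_exmhc	se_exmhc	p_nominal	p_adj
CVID-JIA	0.343	0.127	1.22e-03	0.354	0.142	2.47e-03	2.23e-02
EPI-JIA	-0.150	0.079	2.95e-02	-0.142	0.085	4.87e-02	0.44
EPI-UC	0.197	0.103	2.77e-02	0.248	0.108	1.06e-02	0.10
PS-T1D	-0.241	0.139	3.29e-02	-0.282	0.167	3.74e-02	0.34
PS-UC	-0.316	0.169	2.31e-02	-0.289	0.171	3.76e-02	0.34
SLE-CD	-0.266	0.120	8.25e-03	-0.255	0.121	1.15e-02	0.10
SPA-CD	-0.215	0.138	4.64e-02	-0.235	0.156	4.67e-02	0.42
T1D-CD	0.096	0.053	3.45e-02	0.142	0.064	1.33e-02	0.12
UC-CD	0.659	0.069	1.00e-04	0.674	0.072	1.00e-04	9.00e-04
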