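disease	full_name	cases	controls	gif	prevalence
CD	Crohn's disease	1848	27457	1.086	3.00e-03
CEL	Celiac disease	137	27435	1.006	1.00e-02
CVID	Common variable immunodeficiency disorder	304	27492	1.010	1.00e-04
EPI	Epilepsy	754	26122	1.027	1.00e-04
JIA	Juvenile idiopathic arthritis	1112	27131	1.000	2.00e-03
PS	Psoriasis	85	27474	1.012	1.00e-03
SLE	Systemic lupus erythematosus	252	27525	1.019	1.00e-04
SPA	Spondyloarthropathy	98	27483	1.020	1.00e-04
T1D	Type 1 diabetes	664	27395	1.062	5.00e-03
UC	Ulcerative colitis	854	27482	1.041	1.00e-03
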