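# One-sided association P-values for SNP rs2535629 across five psychiatric
# disorders and their combined analysis (Psychiatric Genomics Consortium
# case/control counts, public summary statistics).
label	cases	controls	p_one_sided
ADHD	2787	2635	0.1005
ASD	4949	5314	0.098
BP	6990	4820	3.305e-06
MDD	9227	7383	0.000108
Schizophrenia	9379	7736	3.355e-05
All	33332	27888	1.27e-12
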