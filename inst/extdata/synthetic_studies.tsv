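# synthetic replication-study table
label	cases	controls	p_one_sided
study_1	8870	11919	0.005183
study_2	5841	5800	5.196e-06
study_3	9698	9774	3.335e-05
study_4	6977	11347	0.0001588
study_5	9176	4121	1.192e-06
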