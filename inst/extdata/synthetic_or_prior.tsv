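# synthetic L-shaped odds-ratio effect-size table
# M=300000
or	count
1.05	2348
1.10	1324
1.15	460
1.20	188
1.30	41
1.50	7
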