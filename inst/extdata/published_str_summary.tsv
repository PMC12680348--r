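quantity	value
str_mean_s_scaled	0.00038
str_mutations_per_generation	13.78
str_total_burden_scaled	0.0062
noncoding_burden_20pct	0.00571
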