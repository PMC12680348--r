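label	mean_s	mutations_per_generation
nonsynonymous	0.0066	0.56
conserved_noncoding	0.00056	2.54
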