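preset	step_height	step_height_reduction	step_factor	step_factor_reduction	enrichment_factor
very sensitive	0.1	0.09	1.5	0.5	1.5
sensitive	0.2	0.15	1.5	0.5	1.8
default	0.3	0.2	2.0	0.5	2.0
specific	0.5	0.3	2.0	0.5	2.0
very specific	1.0	0.5	2.0	0.5	3.0
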