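drug	a1	a2	b1	b2
isotretinoin	423	253	6044	7457
etanercept	614	1168	43723	124146
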