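orientation	context_id	unit_id	a1	a2	b1	b2
by_drug	liver toxicity	acetaminophen	1032	1789	46798	51289
by_drug	liver toxicity	aspirin	135	94	47695	52984
by_drug	liver toxicity	ibuprofen	264	372	47566	52706
by_drug	liver toxicity	meloxicam	12	34	47818	53044
by_drug	liver toxicity	etodolac	9	25	47821	53053
by_drug	liver toxicity	indomethacin	10	25	47820	53053
by_drug	liver toxicity	ketoprofen	9	5	47821	53073
by_drug	liver toxicity	diclofenac	205	256	47625	52822
by_drug	liver toxicity	ketorolac	6	11	47824	53067
by_drug	liver toxicity	piroxicam	9	15	47821	53063
by_drug	liver toxicity	nabumetone	5	9	47825	53069
by_drug	liver toxicity	naproxen	80	96	47750	52982
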