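cow_id	group	avg_heat_score
d0_5006	day0	0
d0_9284	day0	37
d0_3739	day0	43
d0_8855	day0	53
d0_1194	day0	137
d0_1821	day0	175
d0_8870	day0	191
d0_5507	day0	200
d0_1786	day0	206
d0_3472	day0	246
d0_6487	day0	248
d0_3747	day0	378
d0_7008	day0	405
d0_5125	day0	1750
d12_1528	day12	2
d12_9303	day12	4
d12_8860	day12	5
d12_1773	day12	75
d12_8873	day12	157
d12_7724	day12	198
d12_1520	day12	257
d12_7942	day12	275
d12_1607	day12	318
d12_1822	day12	368
d12_1638	day12	383
d12_6956	day12	404
d12_8857	day12	475
d12_2540	day12	505
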