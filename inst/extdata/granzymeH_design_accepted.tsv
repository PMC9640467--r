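step	mutation	sequence
2	G-6-[ORN]	PTSYA[ORN]DDS
14	[ORN]-6-[41 H]	PTSYA[41 H]DDS
27	[ASP]-8-[G5G]	PTSYA[41 H]D[G5G]S
33	[G5G]-8-[C1J]	PTSYA[41 H]D[C1J]S
36	[C1J]-8-[KHB]	PTSYA[41 H]D[KHB]S
40	T-2-[MKD]	P[MKD]SYA[41 H]D[KHB]S
86	[KHB]-8-[54 C]	P[MKD]SYA[41 H]D[54 C]S
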