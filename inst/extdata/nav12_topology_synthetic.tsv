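# Synthetic best-effort topology for the Na_V_1.2 channel alpha-subunit
# (SCN2A, 2005 aa). UniProt-style feature intervals: four homologous domains
# (DI-DIV) of six transmembrane helices (S1-S6) each, an intramembrane
# pore-forming feature between S5 and S6 of every domain, and
# cytoplasmic/extracellular stretches covering the rest of the chain.
# Boundaries are plausible reconstructions, NOT measured coordinates;
# boundary-sensitive analyses should treat them as approximate.
# Coordinates are 1-based inclusive.
region	segment	start	end
cytoplasmic	N-term	1	124
DI	S1	125	147
extracellular	loop	148	154
DI	S2	155	176
cytoplasmic	loop	177	189
DI	S3	190	212
extracellular	loop	213	218
DI	S4	219	238
cytoplasmic	loop	239	252
DI	S5	253	276
extracellular	loop	277	289
DI	pore	290	311
extracellular	loop	312	322
DI	S6	323	348
cytoplasmic	linker	349	752
DII	S1	753	775
extracellular	loop	776	782
DII	S2	783	805
cytoplasmic	loop	806	817
DII	S3	818	840
extracellular	loop	841	845
DII	S4	846	866
cytoplasmic	loop	867	871
DII	S5	872	895
extracellular	loop	896	924
DII	pore	925	946
extracellular	loop	947	954
DII	S6	955	982
cytoplasmic	linker	983	1199
DIII	S1	1200	1222
extracellular	loop	1223	1229
DIII	S2	1230	1252
cytoplasmic	loop	1253	1264
DIII	S3	1265	1287
extracellular	loop	1288	1294
DIII	S4	1295	1320
cytoplasmic	loop	1321	1341
DIII	S5	1342	1365
extracellular	loop	1366	1449
DIII	pore	1450	1471
extracellular	loop	1472	1481
DIII	S6	1482	1510
cytoplasmic	linker	1511	1529
DIV	S1	1530	1552
extracellular	loop	1553	1559
DIV	S2	1560	1582
cytoplasmic	loop	1583	1594
DIV	S3	1595	1617
extracellular	loop	1618	1622
DIV	S4	1623	1645
cytoplasmic	loop	1646	1659
DIV	S5	1660	1683
extracellular	loop	1684	1699
DIV	pore	1700	1721
extracellular	loop	1722	1754
DIV	S6	1755	1780
cytoplasmic	C-term	1781	2005
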