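gene	alt_symbol	chr	n_snps	start	stop	discovery	fluid_p	cryst_p	general_p
HIST3H3	HIST3H3	1	48	226679168	226679649	ngs	0.203	0.734	0.305
RGS7	RGS7	1	804	239005439	239587101	ngs	0.983	0.997	0.998
ST3GAL3	ST3GAL3	1	233	43945804	44169418	ngs	0.378	0.025	0.084
ADRA2B	ADRA2B	2	29	96142349	96145615	ngs	0.091	0.599	0.538
EEF1B2	EEF1B2	2	67	206732562	206735898	ngs	0.747	0.444	0.829
INPP4A	INPP4A	2	117	98427844	98570598	ngs	0.138	0.89	0.338
PECR	PECR	2	130	216611355	216654777	ngs	0.221	0.379	0.146
CRBN	CRBN	3	132	3166695	3196390	homozygosity_mapping	0.883	0.299	0.508
CCNA2	CCNA2	4	74	122957048	122964538	ngs	0.016	0.054	0.016
LOC90826	PRMT10	4	55	148778982	148824730	ngs	0.482	0.116	0.221
PRSS12	PRSS12	4	134	119421864	119493370	homozygosity_mapping	0.06	0.404	0.253
NDST1	NDST1	5	99	149880622	149917966	ngs	0.661	0.185	0.753
ASCC3	ASCC3	6	404	101063328	101435945	ngs	0.128	0.575	0.456
GRIK2	GRIK2	6	868	101953625	102624651	homozygosity_mapping	0.435	0.775	0.802
MED23	MED23	6	104	131936798	131991056	homozygosity_mapping	0.982	0.598	0.94
CASP2	CASP2	7	69	142695523	142714907	ngs	0.885	0.502	0.96
C8orf41	TTI2	8	109	33475777	33490245	ngs	0.014	0.313	0.041
NIBP	TRAPPC9	8	738	140811769	141537860	homozygosity_mapping	0.732	0.851	0.685
TUSC3	TUSC3	8	490	15442100	15666366	homozygosity_mapping	0.105	0.441	0.129
C9orf86	RABL6	9	57	138822201	138855460	ngs	0.979	0.822	0.982
MAN1B1	MAN1B1	9	41	139101199	139123460	ngs	0.947	0.809	0.925
RALGDS	RALGDS	9	104	134962927	135014409	ngs	0.893	0.995	0.992
ADK	ADK	10	376	75580970	76139066	ngs	0.983	0.312	0.996
ENTPD1	ENTPD1	10	220	97461525	97627013	ngs	0.642	0.455	0.444
C11orf46	C11orf46	11	110	30301224	30315741	ngs	0.680	0.663	0.375
ASCL1	ASCL1	12	11	101875581	101878424	ngs	0.950	0.05	0.508
COQ5	COQ5	12	66	119425464	119451347	ngs	0.553	0.397	0.445
CRADD	CRADD	12	239	92595281	92768662	ngs	0.485	0.239	0.272
KIAA1033	KIAA1033	12	159	104025621	104087036	ngs	0.567	0.265	0.427
ZCCHC8	ZCCHC8	12	41	121523387	121551471	ngs	0.549	0.204	0.326
UBR7	UBR7	14	91	92743153	92765314	ngs	0.751	0.886	0.703
ZC3H14	ZC3H14	14	71	88099066	88149606	homozygosity_mapping	0.904	0.292	0.585
SCAPER	SCAPER	15	298	74427591	74963247	ngs	0.298	0.051	0.037
PRRT2	PRRT2	16	17	29730909	29734703	ngs	0.393	0.471	0.705
FASN	FASN	17	52	77629502	77649395	ngs	0.514	0.276	0.510
ELP2	ELP2	18	144	31963884	32008605	ngs	0.044	0.123	0.248
CC2D1A	CC2D1A	19	35	13878051	13902692	homozygosity_mapping	0.657	0.722	0.734
GPSN2	TECR	19	68	14501381	14537792	ngs	0.074	0.223	0.104
TRMT1	TRMT1	19	32	13076714	13088332	ngs	0.633	0.811	0.657
ZNF526	ZNF526	19	16	47416331	47424193	ngs	0.509	0.595	0.627
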