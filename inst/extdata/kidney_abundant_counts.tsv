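mirna_id	isomirs	IB	WB	LD	LW	PT	ME	VT
Hsa-miR-200b-3p	123	239	4924	4298	5163	3683	6987	1803
Ssc-miR-125b	51	567	1245	933	2170	2322	798	774
Ssc-miR-23b	59	116	992	638	935	1090	673	968
Ssc-miR-126	49	158	928	419	1308	1186	660	615
Ssc-miR-23a	51	123	828	535	801	1015	598	1256
Ssc-miR-192	41	89	723	194	1105	810	484	458
Ssc-miR-99a	32	339	615	375	884	888	234	446
Hsa-miR-200c-3p	32	42	367	309	1076	762	631	291
Ssc-miR-10b	31	69	589	271	504	519	561	333
Ssc-miR-126*	26	60	440	387	503	599	418	389
Ssc-miR-30d	31	82	223	142	757	434	238	101
Ssc-miR-125a	29	103	192	194	308	288	173	111
Ssc-miR-10a	19	43	287	176	219	188	284	120
Ssc-miR-365-3p	16	10	168	173	225	246	100	64
Ssc-miR-92a	17	12	96	105	217	125	145	97
Ssc-miR-204	14	10	61	271	173	133	58	42
Ssc-miR-378	20	67	127	52	179	148	103	67
Ssc-miR-26a	17	3	94	76	159	134	91	41
Bta-miR-200a	9	18	87	99	95	58	101	27
Bta-miR-193b	26	69	73	83	102	78	36	32
Ssc-miR-30e-5p	14	27	57	43	134	93	56	51
Ssc-miR-100	6	20	55	72	92	83	39	44
Ssc-miR-99b	8	15	43	47	102	73	28	42
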