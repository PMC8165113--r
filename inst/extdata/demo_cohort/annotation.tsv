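gene_id	symbol	chromosome
G00001	SYM1	11
G00002	SYM2	5
G00003	SYM3	6
G00004	SYM4	16
G00005	SYM5	19
G00006	SYM6	5
G00007	SYM7	6
G00008	SYM8	15
G00009	SYM9	20
G00010	SYM10	17
G00011	SYM11	10
G00012	SYM12	5
G00013	SYM13	21
G00014	SYM14	19
G00015	SYM15	4
G00016	SYM16	13
G00017	SYM17	13
G00018	SYM18	18
G00019	SYM19	18
G00020	SYM20	14
G00021	SYM21	16
G00022	SYM22	21
G00023	SYM23	13
G00024	SYM24	11
G00025	SYM25	10
G00026	SYM26	20
G00027	SYM27	12
G00028	SYM28	1
G00029	SYM29	9
G00030	SYM30	4
G00031	SYM31	19
G00032	SYM32	13
G00033	SYM33	2
G00034	SYM34	15
G00035	SYM35	2
G00036	SYM36	X
G00037	SYM37	X
G00038	SYM38	X
G00039	SYM39	X
G00040	SYM40	X
G00041	SYM41	Y
G00042	SYM42	Y
G00043	SYM43	Y
G00044	SYM44	Y
G00045	SYM45	Y
G00046	SYM46	2
G00047	SYM47	12
G00048	SYM48	18
G00049	SYM49	7
G00050	SYM50	12
G00051	SYM51	12
G00052	SYM52	13
G00053	SYM53	2
G00054	SYM54	3
G00055	SYM55	12
G00056	SYM56	6
G00057	SYM57	15
G00058	SYM58	1
G00059	SYM59	1
G00060	SYM60	17
G00061	SYM61	14
G00062	SYM62	7
G00063	SYM63	15
G00064	SYM64	2
G00065	SYM65	11
G00066	SYM66	9
G00067	SYM67	4
G00068	SYM68	13
G00069	SYM69	1
G00070	SYM70	15
G00071	SYM71	13
G00072	SYM72	4
G00073	SYM73	4
G00074	SYM74	2
G00075	SYM75	1
G00076	SYM76	10
G00077	SYM77	4
G00078	SYM78	17
G00079	SYM79	8
G00080	SYM80	3
G00081	SYM81	15
G00082	SYM82	21
G00083	SYM83	14
G00084	SYM84	11
G00085	SYM85	3
G00086	SYM86	10
G00087	SYM87	14
G00088	SYM88	19
G00089	SYM89	5
G00090	SYM90	11
G00091	SYM91	8
G00092	SYM92	3
G00093	SYM93	21
G00094	SYM94	7
G00095	SYM95	20
G00096	SYM96	9
G00097	SYM97	22
G00098	SYM98	10
G00099	SYM99	14
G00100	SYM100	13
G00101	SYM101	16
G00102	SYM102	7
G00103	SYM103	22
G00104	SYM104	21
G00105	SYM105	19
G00106	SYM106	7
G00107	SYM107	22
G00108	SYM108	5
G00109	SYM109	11
G00110	SYM110	8
G00111	SYM111	12
G00112	SYM112	13
G00113	SYM113	12
G00114	SYM114	21
G00115	SYM115	2
G00116	SYM116	17
G00117	SYM117	10
G00118	SYM118	15
G00119	SYM119	9
G00120	SYM120	13
G00121	SYM121	3
G00122	SYM122	15
G00123	SYM123	5
G00124	SYM124	1
G00125	SYM125	12
G00126	SYM126	20
G00127	SYM127	15
G00128	SYM128	15
G00129	SYM129	10
G00130	SYM130	17
G00131	SYM131	7
G00132	SYM132	17
G00133	SYM133	16
G00134	SYM134	20
G00135	SYM135	6
G00136	SYM136	1
G00137	SYM137	15
G00138	SYM138	19
G00139	SYM139	1
G00140	SYM140	18
G00141	SYM141	21
G00142	SYM142	13
G00143	SYM143	4
G00144	SYM144	17
G00145	SYM145	18
G00146	SYM146	8
G00147	SYM147	14
G00148	SYM148	1
G00149	SYM149	20
G00150	SYM150	3
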