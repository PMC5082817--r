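SIG001	C7	GENE00001	GENE00017	GENE00043	GENE00056	GENE00061	GENE00066	GENE00072	GENE00093	GENE00149	GENE00160	GENE00164	GENE00168	GENE00190	GENE00196	GENE00203	GENE00216	GENE00227	GENE00248	GENE00258	GENE00263	GENE00266	GENE00268	GENE00277	GENE00285	GENE00286
SIG002	C7	GENE00012	GENE00025	GENE00067	GENE00082	GENE00088	GENE00093	GENE00128	GENE00147	GENE00155	GENE00156	GENE00161	GENE00163	GENE00170	GENE00175	GENE00189	GENE00201	GENE00222	GENE00223	GENE00234	GENE00244	GENE00264	GENE00282	GENE00288	GENE00294	GENE00295
SIG003	C7	GENE00015	GENE00041	GENE00052	GENE00058	GENE00075	GENE00099	GENE00105	GENE00115	GENE00126	GENE00128	GENE00143	GENE00153	GENE00155	GENE00185	GENE00189	GENE00190	GENE00191	GENE00197	GENE00203	GENE00237	GENE00258	GENE00265	GENE00281	GENE00283	GENE00299
SIG004	C7	GENE00014	GENE00036	GENE00042	GENE00048	GENE00052	GENE00083	GENE00093	GENE00096	GENE00097	GENE00102	GENE00127	GENE00132	GENE00154	GENE00171	GENE00179	GENE00213	GENE00214	GENE00227	GENE00228	GENE00229	GENE00244	GENE00265	GENE00272	GENE00275	GENE00300
SIG005	C7	GENE00055	GENE00061	GENE00065	GENE00066	GENE00068	GENE00075	GENE00080	GENE00098	GENE00103	GENE00114	GENE00119	GENE00133	GENE00141	GENE00162	GENE00164	GENE00167	GENE00170	GENE00177	GENE00186	GENE00216	GENE00217	GENE00228	GENE00268	GENE00277	GENE00286
SIG006	C7	GENE00015	GENE00017	GENE00037	GENE00039	GENE00040	GENE00041	GENE00052	GENE00058	GENE00066	GENE00077	GENE00078	GENE00079	GENE00094	GENE00101	GENE00109	GENE00128	GENE00135	GENE00144	GENE00150	GENE00171	GENE00177	GENE00205	GENE00216	GENE00235	GENE00275
SIG007	C7	GENE00010	GENE00020	GENE00036	GENE00037	GENE00048	GENE00059	GENE00088	GENE00096	GENE00115	GENE00138	GENE00164	GENE00176	GENE00201	GENE00204	GENE00211	GENE00213	GENE00220	GENE00223	GENE00231	GENE00240	GENE00251	GENE00266	GENE00267	GENE00275	GENE00277
SIG008	C7	GENE00008	GENE00029	GENE00039	GENE00056	GENE00072	GENE00076	GENE00079	GENE00086	GENE00088	GENE00107	GENE00154	GENE00155	GENE00156	GENE00157	GENE00175	GENE00183	GENE00202	GENE00203	GENE00207	GENE00218	GENE00224	GENE00234	GENE00266	GENE00276	GENE00283
SIG009	C7	GENE00001	GENE00013	GENE00043	GENE00047	GENE00075	GENE00082	GENE00090	GENE00093	GENE00108	GENE00114	GENE00115	GENE00127	GENE00141	GENE00149	GENE00164	GENE00167	GENE00170	GENE00203	GENE00216	GENE00235	GENE00258	GENE00264	GENE00273	GENE00286	GENE00287
SIG010	C7	GENE00005	GENE00022	GENE00034	GENE00042	GENE00050	GENE00073	GENE00083	GENE00094	GENE00099	GENE00116	GENE00138	GENE00139	GENE00150	GENE00162	GENE00169	GENE00170	GENE00183	GENE00199	GENE00204	GENE00238	GENE00246	GENE00256	GENE00266	GENE00268	GENE00285
SIG011	C7	GENE00001	GENE00032	GENE00054	GENE00075	GENE00080	GENE00094	GENE00098	GENE00100	GENE00105	GENE00112	GENE00124	GENE00130	GENE00138	GENE00140	GENE00147	GENE00164	GENE00183	GENE00220	GENE00233	GENE00249	GENE00255	GENE00269	GENE00272	GENE00294	GENE00300
SIG012	C7	GENE00045	GENE00062	GENE00066	GENE00070	GENE00073	GENE00075	GENE00104	GENE00116	GENE00121	GENE00130	GENE00141	GENE00142	GENE00181	GENE00183	GENE00199	GENE00203	GENE00213	GENE00218	GENE00223	GENE00229	GENE00236	GENE00257	GENE00265	GENE00288	GENE00296
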