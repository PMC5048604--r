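sample_id	karyotype	twin	outlier
S001	euploid	0	0
S002	euploid	0	0
S003	euploid	0	0
S004	euploid	0	0
S005	euploid	0	0
S006	euploid	0	0
S007	euploid	0	0
S008	euploid	0	0
S009	euploid	0	0
S010	euploid	0	0
S011	euploid	0	0
S012	euploid	0	0
S013	euploid	0	0
S014	euploid	0	0
S015	euploid	0	0
S016	euploid	0	0
S017	euploid	0	0
S018	euploid	0	0
S019	euploid	0	0
S020	euploid	0	0
S021	euploid	0	0
S022	euploid	0	0
S023	euploid	0	0
S024	euploid	0	0
S025	euploid	0	0
S026	euploid	0	0
S027	euploid	0	0
S028	euploid	0	0
S029	euploid	0	0
S030	euploid	0	0
S031	euploid	0	0
S032	euploid	0	0
S033	euploid	0	0
S034	euploid	0	0
S035	euploid	0	0
S036	euploid	0	0
S037	euploid	0	0
S038	euploid	0	0
S039	euploid	0	0
S040	euploid	0	0
S041	euploid	0	0
S042	euploid	0	0
S043	euploid	0	0
S044	euploid	0	0
S045	euploid	0	0
S046	euploid	0	0
S047	euploid	0	0
S048	euploid	0	0
S049	euploid	0	0
S050	euploid	0	0
S051	euploid	0	0
S052	euploid	0	0
S053	euploid	0	0
S054	euploid	0	0
S055	euploid	0	0
S056	euploid	0	0
S057	euploid	0	0
S058	euploid	0	0
S059	euploid	0	0
S060	euploid	0	0
S061	euploid	0	0
S062	euploid	0	0
S063	euploid	0	0
S064	euploid	0	0
S065	euploid	0	0
S066	euploid	0	0
S067	euploid	0	0
S068	euploid	0	0
S069	euploid	0	0
S070	euploid	0	0
S071	euploid	0	0
S072	euploid	0	0
S073	euploid	0	0
S074	euploid	0	0
S075	euploid	0	0
S076	euploid	0	0
S077	euploid	0	0
S078	euploid	0	0
S079	euploid	0	0
S080	euploid	0	0
S081	euploid	0	0
S082	euploid	0	0
S083	euploid	0	0
S084	euploid	0	0
S085	euploid	0	0
S086	euploid	0	0
S087	euploid	0	0
S088	euploid	0	0
S089	euploid	0	0
S090	euploid	0	0
S091	euploid	0	0
S092	euploid	0	0
S093	euploid	0	0
S094	euploid	0	0
S095	euploid	0	0
S096	euploid	0	0
S097	euploid	0	0
S098	euploid	0	0
S099	euploid	0	0
S100	euploid	0	0
S101	euploid	0	0
S102	euploid	0	0
S103	euploid	0	0
S104	euploid	0	0
S105	euploid	0	0
S106	euploid	0	0
S107	euploid	0	0
S108	euploid	0	0
S109	euploid	0	0
S110	euploid	0	0
S111	euploid	0	0
S112	euploid	0	0
S113	euploid	0	0
S114	euploid	0	0
S115	euploid	0	0
S116	euploid	0	0
S117	euploid	0	0
S118	euploid	0	0
S119	euploid	0	0
S120	euploid	0	0
S121	euploid	0	0
S122	euploid	0	0
S123	euploid	0	0
S124	euploid	0	0
S125	euploid	0	0
S126	euploid	0	0
S127	euploid	0	0
S128	euploid	0	0
S129	euploid	0	0
S130	euploid	0	0
S131	euploid	0	0
S132	euploid	0	0
S133	euploid	0	0
S134	euploid	0	0
S135	euploid	0	0
S136	euploid	0	0
S137	euploid	0	0
S138	euploid	0	0
S139	euploid	0	0
S140	euploid	0	0
S141	euploid	0	0
S142	euploid	0	0
S143	euploid	0	0
S144	euploid	0	0
S145	euploid	0	0
S146	euploid	0	0
S147	euploid	0	0
S148	euploid	0	0
S149	euploid	0	0
S150	euploid	0	0
S151	euploid	0	0
S152	euploid	0	0
S153	euploid	0	0
S154	euploid	0	0
S155	euploid	0	0
S156	euploid	0	0
S157	euploid	0	0
S158	euploid	0	0
S159	euploid	0	0
S160	euploid	0	0
S161	euploid	0	0
S162	euploid	0	0
S163	euploid	0	0
S164	euploid	0	0
S165	euploid	0	0
S166	euploid	0	0
S167	euploid	0	0
S168	euploid	0	0
S169	euploid	0	0
S170	euploid	0	0
S171	euploid	0	0
S172	euploid	0	0
S173	euploid	0	0
S174	euploid	0	0
S175	euploid	0	0
S176	euploid	0	0
S177	euploid	0	0
S178	euploid	0	0
S179	euploid	0	0
S180	euploid	0	0
S181	euploid	0	0
S182	euploid	0	0
S183	euploid	0	0
S184	euploid	0	0
S185	euploid	0	0
S186	euploid	0	0
S187	euploid	0	0
S188	euploid	0	0
S189	euploid	0	0
S190	euploid	0	0
S191	euploid	0	0
S192	euploid	0	0
S193	euploid	0	0
S194	euploid	0	0
S195	euploid	0	0
S196	euploid	0	0
S197	euploid	0	0
S198	euploid	0	0
S199	euploid	0	0
S200	euploid	0	0
S201	euploid	0	0
S202	euploid	0	0
S203	euploid	0	0
S204	euploid	0	0
S205	euploid	0	0
S206	euploid	0	0
S207	euploid	0	0
S208	euploid	0	0
S209	euploid	0	0
S210	euploid	0	0
S211	euploid	0	0
S212	euploid	0	0
S213	euploid	0	0
S214	euploid	0	0
S215	euploid	0	0
S216	euploid	0	0
S217	euploid	0	0
S218	euploid	0	0
S219	euploid	0	0
S220	euploid	0	0
S221	euploid	0	0
S222	euploid	0	0
S223	euploid	0	0
S224	euploid	0	0
S225	euploid	0	0
S226	euploid	0	0
S227	euploid	0	0
S228	euploid	0	0
S229	euploid	0	0
S230	euploid	0	0
S231	euploid	0	0
S232	euploid	0	0
S233	euploid	0	0
S234	euploid	0	0
S235	euploid	0	0
S236	euploid	0	0
S237	euploid	0	0
S238	euploid	0	0
S239	euploid	0	0
S240	euploid	0	0
S241	euploid	0	0
S242	euploid	0	0
S243	euploid	0	0
S244	euploid	0	0
S245	euploid	0	0
S246	euploid	0	0
S247	euploid	0	0
S248	euploid	0	0
S249	euploid	0	0
S250	euploid	0	0
S251	euploid	0	0
S252	euploid	0	0
S253	euploid	0	0
S254	euploid	0	0
S255	euploid	0	0
S256	euploid	0	0
S257	euploid	0	0
S258	euploid	0	0
S259	euploid	0	0
S260	euploid	0	0
S261	euploid	0	0
S262	euploid	0	0
S263	euploid	0	0
S264	euploid	0	0
S265	euploid	0	0
S266	euploid	0	0
S267	euploid	0	0
S268	euploid	0	0
S269	euploid	0	0
S270	euploid	0	0
S271	euploid	0	0
S272	euploid	0	0
S273	euploid	0	0
S274	euploid	0	0
S275	euploid	0	0
S276	euploid	0	0
S277	euploid	0	0
S278	euploid	0	0
S279	euploid	0	0
S280	euploid	0	0
S281	euploid	0	0
S282	euploid	0	0
S283	euploid	0	0
S284	euploid	0	0
S285	euploid	0	0
S286	euploid	0	0
S287	euploid	0	0
S288	euploid	0	0
S289	euploid	0	0
S290	euploid	0	0
S291	euploid	0	0
S292	euploid	0	0
S293	euploid	0	0
S294	euploid	0	0
S295	euploid	0	0
S296	euploid	0	0
S297	euploid	0	0
S298	euploid	0	0
S299	euploid	0	0
S300	euploid	0	0
S301	euploid	0	0
S302	euploid	0	0
S303	euploid	0	0
S304	euploid	0	0
S305	euploid	0	0
S306	euploid	0	0
S307	euploid	0	0
S308	euploid	0	0
S309	euploid	0	0
S310	euploid	0	0
S311	euploid	0	0
S312	euploid	0	0
S313	euploid	0	0
S314	euploid	0	0
S315	euploid	0	0
S316	euploid	0	0
S317	euploid	0	0
S318	euploid	0	0
S319	euploid	0	0
S320	euploid	0	0
S321	euploid	0	0
S322	euploid	0	0
S323	euploid	0	0
S324	euploid	0	0
S325	euploid	0	0
S326	euploid	0	0
S327	euploid	0	0
S328	euploid	0	0
S329	euploid	0	0
S330	euploid	0	0
S331	euploid	0	0
S332	euploid	0	0
S333	euploid	0	0
S334	euploid	0	0
S335	euploid	0	0
S336	euploid	0	0
S337	euploid	0	0
S338	euploid	0	0
S339	euploid	0	0
S340	euploid	0	0
S341	euploid	0	0
S342	euploid	0	0
S343	euploid	0	0
S344	euploid	0	0
S345	euploid	0	0
S346	euploid	0	0
S347	euploid	0	0
S348	euploid	0	0
S349	euploid	0	0
S350	euploid	0	0
S351	euploid	0	0
S352	euploid	0	0
S353	euploid	0	0
S354	euploid	0	0
S355	euploid	0	0
S356	euploid	0	0
S357	euploid	0	0
S358	euploid	0	0
S359	euploid	0	0
S360	euploid	0	0
S361	euploid	0	0
S362	euploid	0	0
S363	euploid	0	0
S364	euploid	0	0
S365	euploid	0	0
S366	euploid	0	0
S367	euploid	0	0
S368	euploid	0	0
S369	euploid	0	0
S370	euploid	0	0
S371	euploid	0	0
S372	euploid	0	0
S373	euploid	0	0
S374	euploid	0	0
S375	euploid	0	0
S376	euploid	0	0
S377	euploid	0	0
S378	euploid	0	0
S379	euploid	0	0
S380	euploid	0	0
S381	euploid	0	0
S382	euploid	0	0
S383	euploid	0	0
S384	euploid	0	0
S385	euploid	0	0
S386	euploid	0	0
S387	euploid	0	0
S388	euploid	0	0
S389	euploid	0	0
S390	euploid	0	0
S391	euploid	0	0
S392	euploid	0	0
S393	euploid	0	0
S394	euploid	0	0
S395	euploid	0	0
S396	euploid	0	0
S397	euploid	1	0
S398	euploid	1	0
S399	euploid	1	0
S400	euploid	1	0
S401	euploid	1	0
S402	euploid	1	0
S403	euploid	1	0
S404	euploid	1	0
S405	euploid	1	0
S406	euploid	1	0
S407	euploid	1	0
S408	euploid	1	0
S409	euploid	1	0
S410	euploid	1	0
S411	euploid	1	0
S412	euploid	1	0
S413	euploid	1	0
S414	euploid	1	0
S415	euploid	1	0
S416	euploid	1	0
S417	euploid	1	0
S418	euploid	1	0
S419	euploid	1	0
S420	euploid	1	0
S421	euploid	1	0
S422	euploid	1	0
S423	euploid	1	0
S424	euploid	1	0
S425	euploid	1	0
S426	euploid	0	1
S427	euploid	0	1
S428	euploid	0	1
S429	euploid	0	1
S430	euploid	0	1
S431	T21	1	0
S432	T21	1	0
S433	T21	1	0
S434	T21	0	0
S435	T21	0	0
S436	T21	0	0
S437	T21	0	0
S438	T21	0	0
S439	T21	0	0
S440	T21	0	0
S441	T21	0	0
S442	T21	0	0
S443	T21	0	0
S444	T18	1	0
S445	T13	0	0
S446	other_aneuploidy	0	0
S447	other_aneuploidy	0	0
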