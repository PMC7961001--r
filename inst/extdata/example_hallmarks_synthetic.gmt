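sustaining_proliferative_signaling	synthetic example hallmark set	G0049	G0485	G0321	G0153	G0074	G0228	G0146	G0122	G0500	G0128	G0303	G0024	G0327	G0356	G0089	G0165	G0110	G0020	G0410	G0370
resisting_cell_death	synthetic example hallmark set	G0020	G0410	G0370	G0367	G0387	G0297	G0486	G0283	G0420	G0109	G0005	G0212	G0418	G0348	G0360	G0259	G0314	G0298	G0489	G0158
inducing_angiogenesis	synthetic example hallmark set	G0298	G0489	G0158	G0299	G0399	G0406	G0467	G0136	G0292	G0324	G0494	G0474	G0470	G0197	G0004	G0226	G0434	G0355	G0215	G0433
genome_instability	synthetic example hallmark set	G0355	G0215	G0433	G0245	G0482	G0114	G0262	G0390	G0130	G0372	G0003	G0374	G0405	G0258	G0358	G0186	G0138	G0040	G0473	G0033
evading_growth_suppressors	synthetic example hallmark set	G0040	G0473	G0033	G0103	G0495	G0455	G0329	G0157	G0076	G0265	G0035	G0221	G0016	G0357	G0220	G0248	G0325	G0118	G0441	G0082
enabling_replicative_immortality	synthetic example hallmark set	G0118	G0441	G0082	G0408	G0369	G0402	G0416	G0484	G0469	G0296	G0149	G0057	G0100	G0466	G0091	G0269	G0181	G0054	G0339	G0288
deregulation_cellular_energetics	synthetic example hallmark set	G0054	G0339	G0288	G0208	G0246	G0060	G0285	G0337	G0108	G0377	G0341	G0126	G0112	G0072	G0392	G0001	G0141	G0206	G0311	G0463
activation_invasion_metastasis	synthetic example hallmark set	G0206	G0311	G0463	G0042	G0378	G0417	G0353	G0251	G0425	G0025	G0371	G0191	G0032	G0391	G0238	G0014	G0111	G0443	G0379	G0395
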