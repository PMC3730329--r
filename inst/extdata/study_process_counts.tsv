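process	subset_count	network_count	activated_count	organized_count
protein modification	573	575	52	49
transport	1002	869	194	133
signaling	954	955	69	87
transcription	595	635	17	48
stress	247	257	15	9
metabolism	1340	1410	58	275
cell cycle	65	68	6	7
reproduction	130	137	6	0
intracellular organization	195	201	27	54
development	338	357	0	0
translation	146	99	50	17
death	31	36	0	3
cytoskeleton	57	59	0	0
ion transport	10	8	2	0
proliferation	3	2	1	0
homeostasis	2	2	0	0
differentiation	6	6	0	0
NaN	161	179	0	1
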