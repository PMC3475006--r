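feature_id	chromosome	start	end
p01	14	38510003	38510062
p02	14	38542068	38542127
p03	14	38555801	38555860
p04	14	38562310	38562358
p05	14	38571564	38571623
p06	14	38581765	38581824
p07	14	38587626	38587685
p08	14	38597108	38597167
p09	14	38602277	38602335
p10	14	38609230	38609289
p11	14	38614898	38614957
p12	14	38626492	38626551
p13	14	38631536	38631595
p14	14	38639169	38639225
p15	14	38646487	38646546
p16	14	38653819	38653878
p17	14	38665516	38665575
p18	14	38670657	38670716
p19	14	38675867	38675926
p20	14	38682480	38682539
p21	14	38686855	38686914
p22	14	38693139	38693198
p23	14	38697285	38697344
p24	14	38701438	38701497
p25	14	38705250	38705309
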