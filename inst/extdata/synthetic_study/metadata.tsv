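sample_id	bird_id	nest_of_origin	nest_of_rearing	age_class	nest_treatment	body_mass_g	tarsus_mm	replicate_id	sample_role
B01_1_D8_r1	B01_1	N01	N01	D8	crossfostered	10.6357268893842		r1	biological
B01_1_D8_r2	B01_1	N01	N01	D8	crossfostered	10.6357268893842		r2	biological
B01_1_D15_r1	B01_1	N01	N01	D15	crossfostered	16.9319706590383	18.6211211082705	r1	biological
B01_1_D15_r2	B01_1	N01	N01	D15	crossfostered	16.9319706590383	18.6211211082705	r2	biological
B01_2_D8_r1	B01_2	N01	N01	D8	crossfostered	12.7572921464184		r1	biological
B01_2_D8_r2	B01_2	N01	N01	D8	crossfostered	12.7572921464184		r2	biological
B01_2_D15_r1	B01_2	N01	N02	D15	crossfostered	17.6560712829	19.1965851495513	r1	biological
B01_2_D15_r2	B01_2	N01	N02	D15	crossfostered	17.6560712829	19.1965851495513	r2	biological
B01_3_D8_r1	B01_3	N01	N01	D8	crossfostered	14.2113154886486		r1	biological
B01_3_D8_r2	B01_3	N01	N01	D8	crossfostered	14.2113154886486		r2	biological
B01_3_D15_r1	B01_3	N01	N01	D15	crossfostered	20.3740686938415	20.4152195026021	r1	biological
B01_3_D15_r2	B01_3	N01	N01	D15	crossfostered	20.3740686938415	20.4152195026021	r2	biological
B01_4_D8_r1	B01_4	N01	N01	D8	crossfostered	12.7941770026933		r1	biological
B01_4_D8_r2	B01_4	N01	N01	D8	crossfostered	12.7941770026933		r2	biological
B01_4_D15_r1	B01_4	N01	N01	D15	crossfostered	18.4737160794795	19.7928106617989	r1	biological
B01_4_D15_r2	B01_4	N01	N01	D15	crossfostered	18.4737160794795	19.7928106617989	r2	biological
B01_5_D8_r1	B01_5	N01	N01	D8	crossfostered	10.2176444997427		r1	biological
B01_5_D8_r2	B01_5	N01	N01	D8	crossfostered	10.2176444997427		r2	biological
B01_5_D15_r1	B01_5	N01	N02	D15	crossfostered	18.9531088961096	19.8906508682281	r1	biological
B01_5_D15_r2	B01_5	N01	N02	D15	crossfostered	18.9531088961096	19.8906508682281	r2	biological
B01_6_D8_r1	B01_6	N01	N01	D8	crossfostered	11.8875220393375		r1	biological
B01_6_D8_r2	B01_6	N01	N01	D8	crossfostered	11.8875220393375		r2	biological
B01_6_D15_r1	B01_6	N01	N02	D15	crossfostered	19.2439450887434	20.1050602257684	r1	biological
B01_6_D15_r2	B01_6	N01	N02	D15	crossfostered	19.2439450887434	20.1050602257684	r2	biological
B02_1_D8_r1	B02_1	N02	N02	D8	crossfostered	12.1289560067243		r1	biological
B02_1_D8_r2	B02_1	N02	N02	D8	crossfostered	12.1289560067243		r2	biological
B02_1_D15_r1	B02_1	N02	N02	D15	crossfostered	18.4514680113587	19.7595486894271	r1	biological
B02_1_D15_r2	B02_1	N02	N02	D15	crossfostered	18.4514680113587	19.7595486894271	r2	biological
B02_2_D8_r1	B02_2	N02	N02	D8	crossfostered	9.86970725257437		r1	biological
B02_2_D8_r2	B02_2	N02	N02	D8	crossfostered	9.86970725257437		r2	biological
B02_2_D15_r1	B02_2	N02	N01	D15	crossfostered	17.7062330441636	19.3434840171915	r1	biological
B02_2_D15_r2	B02_2	N02	N01	D15	crossfostered	17.7062330441636	19.3434840171915	r2	biological
B02_3_D8_r1	B02_3	N02	N02	D8	crossfostered	11.0387875732442		r1	biological
B02_3_D8_r2	B02_3	N02	N02	D8	crossfostered	11.0387875732442		r2	biological
B02_3_D15_r1	B02_3	N02	N02	D15	crossfostered	18.8757001068198	19.7726267828361	r1	biological
B02_3_D15_r2	B02_3	N02	N02	D15	crossfostered	18.8757001068198	19.7726267828361	r2	biological
B02_4_D8_r1	B02_4	N02	N02	D8	crossfostered	11.7922518110736		r1	biological
B02_4_D8_r2	B02_4	N02	N02	D8	crossfostered	11.7922518110736		r2	biological
B02_4_D15_r1	B02_4	N02	N01	D15	crossfostered	17.1217679490596	18.684042165578	r1	biological
B02_4_D15_r2	B02_4	N02	N01	D15	crossfostered	17.1217679490596	18.684042165578	r2	biological
B02_5_D8_r1	B02_5	N02	N02	D8	crossfostered	13.1408574932055		r1	biological
B02_5_D8_r2	B02_5	N02	N02	D8	crossfostered	13.1408574932055		r2	biological
B02_5_D15_r1	B02_5	N02	N02	D15	crossfostered	17.2317777175455	19.0186867576143	r1	biological
B02_5_D15_r2	B02_5	N02	N02	D15	crossfostered	17.2317777175455	19.0186867576143	r2	biological
B02_6_D8_r1	B02_6	N02	N02	D8	crossfostered	13.6986112517451		r1	biological
B02_6_D8_r2	B02_6	N02	N02	D8	crossfostered	13.6986112517451		r2	biological
B02_6_D15_r1	B02_6	N02	N01	D15	crossfostered	19.8037559408517	20.702405720563	r1	biological
B02_6_D15_r2	B02_6	N02	N01	D15	crossfostered	19.8037559408517	20.702405720563	r2	biological
B03_1_D8_r1	B03_1	N03	N03	D8	control	12.466196872574		r1	biological
B03_1_D8_r2	B03_1	N03	N03	D8	control	12.466196872574		r2	biological
B03_1_D15_r1	B03_1	N03	N03	D15	control	17.8536968908216	19.1934912434983	r1	biological
B03_1_D15_r2	B03_1	N03	N03	D15	control	17.8536968908216	19.1934912434983	r2	biological
B03_2_D8_r1	B03_2	N03	N03	D8	control	9.15119796082219		r1	biological
B03_2_D8_r2	B03_2	N03	N03	D8	control	9.15119796082219		r2	biological
B03_2_D15_r1	B03_2	N03	N03	D15	control	17.5474374376661	19.0658291821876	r1	biological
B03_2_D15_r2	B03_2	N03	N03	D15	control	17.5474374376661	19.0658291821876	r2	biological
B03_3_D8_r1	B03_3	N03	N03	D8	control	11.8939846578124		r1	biological
B03_3_D8_r2	B03_3	N03	N03	D8	control	11.8939846578124		r2	biological
B03_3_D15_r1	B03_3	N03	N03	D15	control	19.0644044312022	19.893113992751	r1	biological
B03_3_D15_r2	B03_3	N03	N03	D15	control	19.0644044312022	19.893113992751	r2	biological
B03_4_D8_r1	B03_4	N03	N03	D8	control	11.3406068581337		r1	biological
B03_4_D8_r2	B03_4	N03	N03	D8	control	11.3406068581337		r2	biological
B03_4_D15_r1	B03_4	N03	N03	D15	control	17.8499333675688	18.9801057805208	r1	biological
B03_4_D15_r2	B03_4	N03	N03	D15	control	17.8499333675688	18.9801057805208	r2	biological
B03_5_D8_r1	B03_5	N03	N03	D8	control	14.2103696878857		r1	biological
B03_5_D8_r2	B03_5	N03	N03	D8	control	14.2103696878857		r2	biological
B03_5_D15_r1	B03_5	N03	N03	D15	control	17.562957035602	18.9239521301178	r1	biological
B03_5_D15_r2	B03_5	N03	N03	D15	control	17.562957035602	18.9239521301178	r2	biological
B03_6_D8_r1	B03_6	N03	N03	D8	control	11.0042803566846		r1	biological
B03_6_D8_r2	B03_6	N03	N03	D8	control	11.0042803566846		r2	biological
B03_6_D15_r1	B03_6	N03	N03	D15	control	16.9669383944808	18.8824423989653	r1	biological
B03_6_D15_r2	B03_6	N03	N03	D15	control	16.9669383944808	18.8824423989653	r2	biological
B04_1_D8_r1	B04_1	N04	N04	D8	control	11.3654700535929		r1	biological
B04_1_D8_r2	B04_1	N04	N04	D8	control	11.3654700535929		r2	biological
B04_1_D15_r1	B04_1	N04	N04	D15	control	16.7175737665201	18.6328540173209	r1	biological
B04_1_D15_r2	B04_1	N04	N04	D15	control	16.7175737665201	18.6328540173209	r2	biological
B04_2_D8_r1	B04_2	N04	N04	D8	control	13.5400171000279		r1	biological
B04_2_D8_r2	B04_2	N04	N04	D8	control	13.5400171000279		r2	biological
B04_2_D15_r1	B04_2	N04	N04	D15	control	17.981484382595	19.6121893423286	r1	biological
B04_2_D15_r2	B04_2	N04	N04	D15	control	17.981484382595	19.6121893423286	r2	biological
B04_3_D8_r1	B04_3	N04	N04	D8	control	11.5472004108962		r1	biological
B04_3_D8_r2	B04_3	N04	N04	D8	control	11.5472004108962		r2	biological
B04_3_D15_r1	B04_3	N04	N04	D15	control	19.2881458200336	19.5569856865849	r1	biological
B04_3_D15_r2	B04_3	N04	N04	D15	control	19.2881458200336	19.5569856865849	r2	biological
B04_4_D8_r1	B04_4	N04	N04	D8	control	10.9590065814753		r1	biological
B04_4_D8_r2	B04_4	N04	N04	D8	control	10.9590065814753		r2	biological
B04_4_D15_r1	B04_4	N04	N04	D15	control	16.8718724659591	18.6834075708927	r1	biological
B04_4_D15_r2	B04_4	N04	N04	D15	control	16.8718724659591	18.6834075708927	r2	biological
B04_5_D8_r1	B04_5	N04	N04	D8	control	14.2457239851811		r1	biological
B04_5_D8_r2	B04_5	N04	N04	D8	control	14.2457239851811		r2	biological
B04_5_D15_r1	B04_5	N04	N04	D15	control	17.4922115041521	18.7341805094082	r1	biological
B04_5_D15_r2	B04_5	N04	N04	D15	control	17.4922115041521	18.7341805094082	r2	biological
B04_6_D8_r1	B04_6	N04	N04	D8	control	13.2143764233319		r1	biological
B04_6_D8_r2	B04_6	N04	N04	D8	control	13.2143764233319		r2	biological
B04_6_D15_r1	B04_6	N04	N04	D15	control	18.8474797277482	19.3356172599384	r1	biological
B04_6_D15_r2	B04_6	N04	N04	D15	control	18.8474797277482	19.3356172599384	r2	biological
NEG01									negative_control
NEG02									negative_control
BLANK01									blank
BLANK02									blank
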