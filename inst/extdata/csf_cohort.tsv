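patient_id	isolate_id	collection_route	csf_volume_ml	conc_37	conc_150	conc_300	tissue_h3_status
P01	1	VAD	3	16793	15170	8583	negative
P02	1	VAD	2.4	2972	1486	546	negative
P03	1	VAD	2.8	676	417	306	negative
P04	1	VAD	4	361	122	101	negative
P05	1	VAD	2.5	53	35	20	negative
P06	1	IO	2	0	0	0	negative
P07	1	IO	4	973	683	669	negative
P08	1	IO	4	64	47	142	negative
P09	1	LP	3	16	10	0	positive
P10	1	LP	2	1	3	4	positive
P11	1	IO	13.3	66	108	87	positive
P11	2	IO	13.3	320	165	137	positive
P11	3	LP	1	4	7	3	positive
P12	1	IO	10	27	14	6	positive
P12	2	IO	10	19	8	9	positive
P13	1	VAD	5	106	81	51	unavailable
P14	1	VAD	4.8	387	108	67	negative
P15	1	LP	3.5	0	0	0	negative
P16	1	IO	1.2	0	0	0	negative
P17	1	VAD	2	9	6	0	unavailable
P18	1	LP	2	2	0	0	unavailable
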