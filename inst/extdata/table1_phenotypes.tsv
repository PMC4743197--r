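family_id	individual_id	age_years	sex	ofc_z	consanguineous_parents	affected	hpo_terms
F01	P01	8	female	-3.0	FALSE	TRUE	HP:0000252,HP:0001249
F02	P02	5	female	-5.3	FALSE	TRUE	HP:0000252,HP:0001249
F03	P03	3	female	-6.3	FALSE	TRUE	HP:0000252,HP:0001249
F04	P04	2	male	-4.6	FALSE	TRUE	HP:0000252,HP:0001249
F05	P05	8	male	-3.3	FALSE	TRUE	HP:0000252,HP:0001249
F06	P06	31	female	-5.0	FALSE	TRUE	HP:0000252,HP:0001249
F07	P07	4	male	-3.6	FALSE	TRUE	HP:0000252,HP:0001249
F08	P08	5	female	-4.4	FALSE	TRUE	HP:0000252,HP:0001249
F08	P09	10	female	-5.2	FALSE	TRUE	HP:0000252,HP:0001249
F10	P10	56	female	NA	FALSE	TRUE	HP:0000252,HP:0001249
F10	P11	57	female	-7.1	FALSE	TRUE	HP:0000252,HP:0001249
F12	P12	3	male	-4.6	FALSE	TRUE	HP:0000252,HP:0001249
F13	P13	10	male	-5.0	FALSE	TRUE	HP:0000252,HP:0001249
F14	P14	1	male	-3.2	FALSE	TRUE	HP:0000252,HP:0001249
F15	P15	0.5	female	-7.0	FALSE	TRUE	HP:0000252,HP:0001249
F16	P16	3	male	-3.3	TRUE	TRUE	HP:0000252,HP:0001249
F17	P17	2	female	-3.0	FALSE	TRUE	HP:0000252,HP:0001249
F18	P18	23	male	-3.0	FALSE	TRUE	HP:0000252,HP:0001249
F19	P19	22	female	-4.0	FALSE	TRUE	HP:0000252,HP:0001249
F20	P20	4	male	-3.9	FALSE	TRUE	HP:0000252,HP:0001249
F21	P21	11	female	-4.8	FALSE	TRUE	HP:0000252,HP:0001249
F22	P22	5	female	-8.0	FALSE	TRUE	HP:0000252,HP:0001249
F23	P23	2	male	-4.9	TRUE	TRUE	HP:0000252,HP:0001249
F24	P24	19	female	-3.0	FALSE	TRUE	HP:0000252,HP:0001249
F25	P25	2	male	-4.5	FALSE	TRUE	HP:0000252,HP:0001249
F26	P26	5	female	-3.9	FALSE	TRUE	HP:0000252,HP:0001249
F27	P27	5	male	-4.5	TRUE	TRUE	HP:0000252,HP:0001249
F27	P28	13	female	NA	TRUE	TRUE	HP:0000252,HP:0001249
F29	P29	1	female	-3.0	TRUE	TRUE	HP:0000252,HP:0001249
F30	P30	1	female	-5.2	FALSE	TRUE	HP:0000252,HP:0001249
F31	P31	3	male	-3.4	TRUE	TRUE	HP:0000252,HP:0001249
F32	P32	14	female	-6.8	FALSE	TRUE	HP:0000252,HP:0001249
F33	P33	2	female	-3.1	FALSE	TRUE	HP:0000252,HP:0001249
F34	P34	0	female	-3.9	FALSE	TRUE	HP:0000252,HP:0001249
F35	P35	4	male	-4.4	TRUE	TRUE	HP:0000252,HP:0001249
F36	P36	16	female	-3.7	FALSE	TRUE	HP:0000252,HP:0001249
F37	P37	2	male	-3.5	FALSE	TRUE	HP:0000252,HP:0001249
F38	P38	0.5	male	-5.2	FALSE	TRUE	HP:0000252,HP:0001249
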