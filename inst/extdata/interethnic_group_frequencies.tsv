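population	n	location	g4	g5	g6	g7	g12	g13	g14
Brazilian	964	Brazil	20.4	36.0	18.2	4.2	11.3	7.4	2
Ngawbe	105	Panama	72.4	2.4	0	23.3	0	1.9	NA
Embera	136	Panama	61	9.9	3.7	22.8	0	2.6	NA
Tswana	101	South Africa	13.4	32.2	20	0	20.8	6.4	8.4
San	40	Zimbabwe	23.7	20	20	1.3	23.8	2.5	8.8
Mandenka	97	Senegal	9.3	36.1	17	6.7	15.5	5.2	10.3
Sudanese	127	Sudan	8.7	47.2	28.7	3.1	8.3	0.8	3.1
Spanish	1312	Spain	22.2	45.7	26.7	1.2	2.6	0.3	1.4
French	60	France	18.3	51.7	25	0.8	0	4.2	0
German	844	Germany	22.7	46.5	27.8	1.3	NA	1.5	0.1
UK_Caucasian	112	United Kingdom	19.6	52.7	24.6	2.2	0.4	0.4	0.9
US_Caucasian	387	United States	24.2	45.9	26.6	1.9	0.4	0.9	0.1
Polish	248	Poland	22	44.4	30	3.4	0.2	0	0
Russian	364	Russia	23.5	45.6	27.2	3.2	0.5	0	0
Thai	44	Thailand	29.5	11.4	38.6	19.3	0	1.1	0
Han_Chinese	212	China	59.2	4	20.8	14.9	0.7	0.5	0
Japanese	200	Japan	69.5	0.5	19.8	8.8	NA	1.3	NA
Korean	1000	Korea	66.1	1.6	20.1	11.5	0.8	0.1	0
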