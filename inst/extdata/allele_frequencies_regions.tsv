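region	n_alleles	NAT2*4	NAT2*5A	NAT2*5B	NAT2*5C	NAT2*6A	NAT2*7B	NAT2*12A	NAT2*12B	NAT2*13A	NAT2*14B
North	378	25.1	6.6	27.2	1.6	19.6	7.4	1.3	0.3	2.4	2.4
Northeast	156	19.8	1.9	32	3.2	26.9	5.1	1.9	0	2.6	1.3
Midwest	212	26.8	0.5	29.2	1.4	26.4	4.2	3.3	0	0.9	0.9
Southeast	670	20	1	33.8	2.1	16	3.9	3.4	0.1	11.2	2.4
South	496	14.7	1	23.8	5	9.9	1.2	21	8.4	8.8	0
Total	1912	20.4	2.1	29.3	2.8	17.1	4	7.4	2.3	7	1.5
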