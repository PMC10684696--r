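genotype	n_subjects	freq_pct	printed_class
*4/*4	55	5.7	rapid
*4/*13A	41	4.3	rapid
*12A/*12A	23	2.4	rapid
*13A/*13A	16	1.6	rapid
*12A/*12B	12	1.2	rapid
*4/*12A	11	1.1	rapid
*5B/*5B	109	11.4	slow
*5B/*6A	87	9.1	slow
*6A/*6A	54	5.6	slow
*5B/*7B	25	2.6	slow
*6A/*7B	17	1.8	slow
*5A/*6A	12	1.2	slow
*5B/*5C	12	1.2	slow
*4/*5B	96	10.0	intermediate
*4/*6A	68	7.1	intermediate
*5B/*12A	37	3.9	intermediate
*5B/*13A	30	3.1	intermediate
*5B/*12B	24	2.5	intermediate
*4/*5A	13	1.4	intermediate
*4/*7B	13	1.4	intermediate
*5C/*12A	12	1.2	intermediate
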