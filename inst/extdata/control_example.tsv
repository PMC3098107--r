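gene_id	0	0.5	1	3	6	12	24
AT1G01010	8	8	8	8	8	8	8
AT1G01020	5	6	7	8	9	10	11
AT1G01030	8	9	7	8	7.5	6.5	8.5
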