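line_id	upstream	downstream	intergenic	intronic	utr5	utr3	exonic	frameshift_indel	nonframeshift_indel	nonsynonymous_snv	synonymous_snv	stop_gain	total
TWF1033	1	3	6	1	0	0	0	0	0	0	0	0	11
TWF1034	1	2	5	2	0	0	0	0	0	0	0	0	10
TWF1035	4	4	7	4	1	0	3	1	0	2	0	0	23
TWF1036	5	8	9	2	2	4	8	1	0	6	1	0	38
TWF1037	10	6	28	5	9	7	24	0	0	18	6	0	89
TWF1038	5	6	8	7	2	2	12	0	0	6	5	1	42
TWF1039	2	5	10	0	2	1	10	0	0	7	3	0	30
TWF1040	5	7	5	1	2	1	10	0	0	7	3	0	31
TWF1041	3	5	9	4	4	1	17	1	0	12	4	1	43
TWF1042	13	3	15	8	4	0	26	3	0	14	9	0	69
TWF1043	6	7	11	10	2	2	12	0	0	6	5	1	50
TWF1044	5	2	6	7	4	2	3	0	0	2	1	0	29
TWF1046	14	3	12	11	9	5	26	2	0	9	12	3	80
TWF1073	28	6	4	6	14	4	22	9	3	4	1	5	84
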