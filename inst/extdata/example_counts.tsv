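gene_id	1x1	2x1	3x1	4x1	5x1	1x2	2x2	3x2	4x2	5x2	1x3	2x3	3x3	4x3	5x3	1x4	2x4	3x4	4x4	5x4	1x5	2x5	3x5	4x5	5x5
gene_001_m1	2	2	6	3	3	5	1	7	4	3	5	4	3	4	1	6	9	7	4	4	3	5	5	1	0
gene_002_m1	2	4	3	4	1	7	4	5	1	4	3	11	7	5	5	7	20	18	6	0	3	4	6	1	2
gene_003_m1	3	2	3	3	3	2	3	3	5	4	3	2	12	0	2	11	10	12	1	3	3	5	0	5	3
gene_004_m1	3	4	6	1	0	5	4	2	3	2	3	21	12	1	4	8	7	11	1	10	5	5	6	1	4
gene_005_m2	1	1	4	9	6	3	2	7	10	2	2	5	4	5	0	1	3	10	3	3	4	6	5	3	1
gene_006_m2	1	2	1	12	8	1	2	3	13	3	1	1	7	7	2	4	3	8	3	1	13	6	8	0	0
gene_007_m2	5	2	1	8	2	1	3	2	6	3	2	6	20	3	5	5	6	16	6	2	8	17	6	4	8
gene_008_m2	0	3	3	11	2	1	4	2	11	7	5	2	11	2	0	0	14	5	0	1	5	14	2	0	0
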