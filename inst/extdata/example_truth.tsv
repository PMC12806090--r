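gene_id	module
gene_001_m1	1
gene_002_m1	1
gene_003_m1	1
gene_004_m1	1
gene_005_m2	2
gene_006_m2	2
gene_007_m2	2
gene_008_m2	2
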