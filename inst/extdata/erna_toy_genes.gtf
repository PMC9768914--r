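chrT	toy	gene	10001	15000	.	+	.	gene_id "toygene1"; gene_biotype "protein_coding";
chrT	toy	transcript	10001	15000	.	+	.	gene_id "toygene1"; gene_biotype "protein_coding"; transcript_id "toygene1.t1";
chrT	toy	exon	10001	15000	.	+	.	gene_id "toygene1"; gene_biotype "protein_coding"; transcript_id "toygene1.t1";
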