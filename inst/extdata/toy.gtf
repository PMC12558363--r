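chr1	toy	gene	100	2000	.	+	.	gene_id "GENE1"; gene_name "ALPHA";
chr1	toy	transcript	100	2000	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chr1	toy	exon	100	250	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chr1	toy	exon	600	750	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chr1	toy	exon	1200	1350	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chr1	toy	exon	1800	2000	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t1";
chr1	toy	transcript	100	2000	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t2";
chr1	toy	exon	100	250	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t2";
chr1	toy	exon	1200	1350	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t2";
chr1	toy	exon	1800	2000	.	+	.	gene_id "GENE1"; transcript_id "GENE1.t2";
chr1	toy	gene	5000	7000	.	-	.	gene_id "GENE2"; gene_name "BETA";
chr1	toy	transcript	5000	7000	.	-	.	gene_id "GENE2"; transcript_id "GENE2.t1";
chr1	toy	exon	5000	5200	.	-	.	gene_id "GENE2"; transcript_id "GENE2.t1";
chr1	toy	exon	5600	5700	.	-	.	gene_id "GENE2"; transcript_id "GENE2.t1";
chr1	toy	exon	6500	7000	.	-	.	gene_id "GENE2"; transcript_id "GENE2.t1";
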