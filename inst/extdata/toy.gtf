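chr1	toy	gene	101	700	.	+	.	gene_id "TG1"; gene_name "TOYA"; gene_biotype "protein_coding";
chr1	toy	transcript	101	700	.	+	.	gene_id "TG1"; transcript_id "TG1.T1"; gene_biotype "protein_coding"; transcript_biotype "protein_coding"; transcript_support_level "1"; tag "basic"; tag "MANE_Select";
chr1	toy	exon	101	200	.	+	.	gene_id "TG1"; transcript_id "TG1.T1"; exon_number "1";
chr1	toy	exon	301	400	.	+	.	gene_id "TG1"; transcript_id "TG1.T1"; exon_number "2";
chr1	toy	exon	601	700	.	+	.	gene_id "TG1"; transcript_id "TG1.T1"; exon_number "3";
chr1	toy	transcript	101	400	.	+	.	gene_id "TG1"; transcript_id "TG1.T2"; gene_biotype "protein_coding"; transcript_biotype "protein_coding"; transcript_support_level "5"; tag "basic";
chr1	toy	exon	101	200	.	+	.	gene_id "TG1"; transcript_id "TG1.T2"; exon_number "1";
chr1	toy	exon	301	400	.	+	.	gene_id "TG1"; transcript_id "TG1.T2"; exon_number "2";
chr1	toy	gene	1101	1700	.	-	.	gene_id "TG2"; gene_name "TOYB"; gene_biotype "lncRNA";
chr1	toy	transcript	1101	1700	.	-	.	gene_id "TG2"; transcript_id "TG2.T1"; gene_biotype "lncRNA"; transcript_biotype "lncRNA"; transcript_support_level "NA"; tag "basic";
chr1	toy	exon	1601	1700	.	-	.	gene_id "TG2"; transcript_id "TG2.T1"; exon_number "1";
chr1	toy	exon	1101	1200	.	-	.	gene_id "TG2"; transcript_id "TG2.T1"; exon_number "2";
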