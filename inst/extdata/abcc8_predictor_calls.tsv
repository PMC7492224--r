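variant_id	gene	hgvs_c	hgvs_p	variant_class	gnomad_af	annovar_impact	cadd	sift	polyphen2	mutassessor	fathmm	vest	other_codes
c.211C>T	ABCC8	c.211C>T	p.(His71Tyr)	missense	0	-	Damaging	Damaging	Probably damaging	Damaging	Damaging	Damaging	-
c.298G>A	ABCC8	c.298G>A	p.(Glu100Lys)	missense	0.00007162	MODERATE	Possibly damaging	Benign	Benign	Benign	Damaging	Possibly damaging	-
c.1429G>A	ABCC8	c.1429G>A	p.(Val477Met)	missense	0.000007957	MODERATE	Damaging	Damaging	Damaging	Possibly damaging	Damaging	Damaging	-
c.1643C>T	ABCC8	c.1643C>T	p.(Thr548Met)	missense	0.00006322	MODERATE	Damaging	Damaging	Damaging	Possibly damaging	Damaging	Possibly damaging	-
c.2176G>A	ABCC8	c.2176G>A	p.(Ala726Thr)	missense	0.0004671	MODERATE	Damaging	Benign	Benign	Benign	Damaging	Benign	-
c.2422C>A	ABCC8	c.2422C>A	p.(Gln808Lys)	missense	0.00005303	MODERATE	Damaging	Possibly damaging	Probably damaging	Benign	Damaging	Damaging	-
c.2694+1G>A	ABCC8	c.2694+1G>A	-	intronic_splice	0.000003979	-	Damaging	-	-	-	-	-	-
c.3238G>A	ABCC8	c.3238G>A	p.(Val1080Ile)	missense	0.00003536	MODERATE	Damaging	Benign	Benign	Benign	Damaging	Benign	-
c.3288_3289del	ABCC8	c.3288_3289del	p.(His1097ProfsTer16)	frameshift	0	HIGH	-	-	-	-	-	-	PM2
c.3394G>A	ABCC8	c.3394G>A	p.(Asp1132Asn)	exon_skipping_confirmed	0.00003185	MODERATE	Damaging	Damaging	Damaging	Damaging	Damaging	Possibly damaging	PS3,PM2
c.3976G>A	ABCC8	c.3976G>A	p.(Glu1326Lys)	missense	0.0001452	MODERATE	Damaging	Possibly damaging	Benign	Benign	Damaging	Damaging	-
SMAD1:c.27delinsGTAAAG	SMAD1	c.27delinsGTAAAG	p.(Phe9LeufsTer2)	frameshift	-	-	-	-	-	-	-	-	PM2
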