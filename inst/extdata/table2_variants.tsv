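sample_ids	gene	transcript_id	gnomen	cnomen	pnomen	rsid	vafs	clinvar	gnomad	class	splice_delta	splice_events	insilico	functional_evidence	comment
051783	MLH1	NM_000249.3	Chr3:g.37042548A>G	c.306+4A>G	p.(?)	rs267607733	0.35	6 x VUS	0.0012%	3			SSF=deleterious|MES=deleterious		Activation of a cryptic donor site and the skipping of exon 3 in an ex vivo splicing minigene assay
060337	MLH1	NM_000249.3	Chr3:g.37090414A>G	c.2009A>G	p.(Lys670Arg)	rs905983196	0.49	3 x VUS	NIL	3			UMD=deleterious|MutationTaster=deleterious		SS: Helix
051456	MSH6	NM_000179.2	Chr2:g.48010297G>T	c.-76G>T	p.(?)		0.64	NIL	NIL	3					No frequency, highly conserved
051026	MSH6	NM_000179.2	Chr2:g.48018140A>G	c.335A>G	p.(Asn112Ser)	rs587779934	0.44	6 X VUS	0.0025%	3			UMD=deleterious|MutationTaster=deleterious		New acceptor site predicted SS: Turn
051408	MSH6	NM_000179.2	Chr2:g.48025743C>A	c.628-7C>A	p.(?)	rs373129248	0.41	6 x VUS	0.0093%	3					
051476	MSH6	NM_000179.2	Chr2:g.48026531C>G	c.1409C>G	p.(Ser470*)		0.48	NIL	NIL	5			UMD=deleterious|MutationTaster=deleterious		SS: Helix
051791	MSH6	NM_000179.2	Chr2:g.48027325C>A	c.2203C>A	p.(Leu735Ile)	rs786204071	0.4	6 X VUS	NIL	3			UMD=deleterious|MutationTaster=deleterious		
051280	MSH6	NM_000179.2	Chr2:g.48032048G>T	c.3439-1G>T	p.(?)	rs587779263	0.5	8 X Pathogenic	NIL	5	-1	deactivation			
060162	MSH6	NM_000179.2	Chr2:g.48033587_48033614dup	c.3802-4_3825dup	p.(Glu1276*)		0.46	NIL	NIL	5			UMD=deleterious|MutationTaster=deleterious		
051233	MSH2	NM_000251.2	Chr2:g.47630427A>C	c.97A>C	p.(Thr33Pro)	rs63751107	0.75	6 X VUS	0.0056%	3			UMD=deleterious|PolyPhen=deleterious|SIFT=deleterious|MutationTaster=deleterious		SS: Beta strand; SNPs3D -1.08, reduced mismatch binding/release efficiency in previous studies
051233	MSH3	NM_002439.4	Chr5:g.79968115C>T	c.845C>T	p.(Thr282Ile)	rs202184623	0.67	NIL	0.0053%	3					SS: Beta strand
051872	MSH2	NM_000251.2	Chr2:g.47657032G>T	c.1228G>T	p.(Gly410Cys)	rs587782242	0.47	1 X VUS	NIL	3			UMD=deleterious|PolyPhen=deleterious|SIFT=deleterious|MutationTaster=deleterious		SS: Helix; Grantham 159
051107	MSH2	NM_000251.2	Chr2:g.47672680C>A	c.1277-7C>A	p.(?)	rs375437307	0.57	3 X VUS	0.0037%	3					
051271	MSH2	NM_000251.2	Chr2:g.47710015T>G	c.2732T>G	p.(Leu911Arg)	rs41295182	1	1 X VUS	0.0062%	3			UMD=deleterious|PolyPhen=deleterious|SIFT=deleterious|MutationTaster=deleterious		SS: Helix; Grantham 102; SNPs3D -1.08
051179,051300	PMS2	NM_001322014.1	Chr7:g.6045549C>A	c.137G>T	p.(Ser46Ile)	rs121434629	0.44,0.47	12 X VUS	0.0169%	4			UMD=deleterious|PolyPhen=deleterious|SIFT=deleterious|MutationTaster=deleterious	supports_pathogenic	Associated with diagnosis of CMMRD syndrome, SS: Helix; strongly decreased DNA mismatch repair activity in functional studies
051657	MSH3	NM_002439.4	Chr5:g.80021325A>G	c.1394A>G	p.(Tyr465Cys)	rs35009542	0.58	NIL	0.0202%	3					SS: Helix
051172	MSH3	NM_002439.4	Chr5:g.79974804G>A	c.1232G>A	p.(Arg411His)	rs764885728	0.49	NIL	0.0012%	3					
051469	MSH3	NM_002439.4	Chr5:g.80021327A>G	c.1396A>G	p.(Ser466Gly)	rs766948921	0.51	NIL	0.0025%	3					SS: Helix
060161,051330	MSH3	NM_002439.4	Chr5:g.80063896C>T	c.2041C>T	p.(Pro681Ser)	rs115198722	0.48,0.55	NIL	0.0787%	3					SS: Helix
051610	POLD1	NM_001308632.1	Chr19:g.50905980G>A	c.952G>A	p.(Glu318Lys)	rs775232133	0.63	1 X VUS	NIL	3			UMD=deleterious|MutationTaster=deleterious		Highly conserved; DNA binding cleft of the exonuclease active domain; SNPs3D -2.68
051406	RFC1	NM_001204747.1	Chr4:g.39290383A>T	c.3445T>A	p.(*1149Argext*15)	rs149767968	0.59	NIL	0.0065%	3					Altered stop codon, extension of protein with 15 aa
051406	RPA3	NM_002947.4	Chr7:g.7676702A>G	c.295T>C	p.(Tyr99His)		0.62	NIL	0.0004%	3					SS: Helix
051663	RFC1	NM_001204747.1	Chr4:g.39306530C>A	c.2017G>T	p.(Val673Leu)	rs28903096	0.33	NIL	0.057%	3					
051400	RFC1	NM_001204747.1	Chr4:g.39346049A>C	c.208+972T>G	p.(?)		0.63	NIL	NIL	3		new_donor			Predicted as new donor site
051471	RFC3	NM_002915.3	Chr13:g.34392210A>G	c.-106A>G	p.(?)	rs554574193	0.57	NIL	0.0064%	3					Highly conserved; TFBS hits incl. CREB1
051640	RFC4	NM_002916.3	Chr3:g.186524157G>A	c.-90C>T	p.(?)		0.52	NIL	NIL	3					Not conserved; TFBS hit for AR
051439	RFC4	NM_002916.3	Chr3:g.186518351T>C	c.210+555A>G	p.(?)	rs781729102	0.55	NIL	0.0387%	3		new_donor			Predicted as new donor site
051802	LIG1	NM_000234.2	Chr19:g.48640874G>A	c.1159C>T	p.(Arg387Cys)	rs749929415	0.48	NIL	0.0018%	3					SS: Beta strand
051133	LIG1	NM_002439.4	Chr19:g.48653350A>C	c.692T>G	p.(Phe231Cys)	rs767343361	0.37	NIL	0.0079%	3					SS: Turn
051166	MLH1	NM_000249.3	Chr3:g.37048554G>A	c.453G>A	p.(Thr151=)	rs369521379	0.51	9 x VUS	0.0011%	3	-0.29		UMD=deleterious|SSF=deleterious		Last nucleotide of exon 5; may damage the nearby splice donor site; SS: Beta strand
051166	EXO1	NM_006027.4	Chr1:g.242020650G>T	c.409G>T	p.(Ala137Ser)	rs147663824	0.55	NIL	0.0094%	3					SS: Helix
051166	RPA3	NM_002947.4	Chr7:g.7753847G>T	c.-1028+959C>A	p.(?)		0.51	NIL	NIL	3		cryptic_strong_activation			Predicted strong activation of a cryptic donor site
051267	EXO1	NM_130398.3	Chr1:g.242052986T>G	c.*84T>G	p.(?)		0.5	NIL	NIL	3					Can affect miRNA binding, for miR-370-3p and miR-93-3p
051007	RPA1	NM_002945.4	Chr17:g.1785509A>G	c.1241+1524A>G	p.(?)	rs536796524	0.43	NIL	0.0323%	3		new_acceptor			Within 1000 bp of a region that may be important for chromatin folding (Insulator / CTCF / SMC3 / RAD21)
051291	RPA3	NM_002947.4	Chr7:g.7695875T>C	c.-757-15069A>G	p.(?)	rs946965390	0.54	NIL	NIL	3		new_acceptor			Within 2500 bp of a region that may be important for chromatin folding (Insulator / CTCF / SMC3 / RAD21)
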