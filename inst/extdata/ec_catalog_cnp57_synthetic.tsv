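# Synthetic nutrient-cycling EC catalog: 57 enzyme-commission numbers with
# C/N/P cycle assignments curated from literature-standard soil nutrient
# cycling enzymes. Assembled for this package (synthetic stand-in for a
# study-specific catalog); users may supply their own via ec_catalog().
ec	name	cycles
3.2.1.4	cellulase	C
3.2.1.91	cellulose 1,4-beta-cellobiosidase	C
3.2.1.21	beta-glucosidase	C
3.2.1.8	endo-1,4-beta-xylanase	C
3.2.1.1	alpha-amylase	C
3.2.1.14	chitinase	C
1.10.3.2	laccase	C
1.11.1.7	peroxidase	C
3.2.1.3	glucan 1,4-alpha-glucosidase	C
3.2.1.37	xylan 1,4-beta-xylosidase	C
3.2.1.20	alpha-glucosidase	C
3.2.1.52	beta-N-acetylhexosaminidase	C
3.2.1.78	mannan endo-1,4-beta-mannosidase	C
1.11.1.14	lignin peroxidase	C
1.11.1.13	manganese peroxidase	C
3.2.1.50	alpha-N-acetylglucosaminidase	C
1.7.1.15	nitrite reductase (NADH)	N
1.7.2.1	nitrite reductase (NO-forming)	N
1.7.7.1	ferredoxin-nitrite reductase	N
1.7.99.1	hydroxylamine reductase	N
3.5.1.4	amidase	N
3.5.1.5	urease	N
3.4.11.1	leucyl aminopeptidase	N
3.4.11.2	membrane alanyl aminopeptidase	N
1.18.6.1	nitrogenase	N
1.7.5.1	nitrate reductase (quinone)	N
1.7.2.4	nitrous-oxide reductase	N
1.7.2.5	nitric oxide reductase (cytochrome c)	N
1.4.1.2	glutamate dehydrogenase	N
6.3.1.2	glutamine synthetase	N
1.4.7.1	glutamate synthase (ferredoxin)	N
3.5.5.1	nitrilase	N
1.14.99.39	ammonia monooxygenase	N
1.7.1.4	nitrite reductase (NAD(P)H)	N
3.1.3.1	alkaline phosphatase	P
3.1.3.2	acid phosphatase	P
3.1.3.25	inositol-phosphate phosphatase	P
3.1.3.26	4-phytase	P
3.1.3.8	3-phytase	P
3.1.4.46	glycerophosphodiester phosphodiesterase	P
3.1.4.55	phosphoribosyl 1,2-cyclic phosphate phosphodiesterase	P
3.6.1.1	inorganic diphosphatase	P
3.6.1.11	exopolyphosphatase	P
3.6.1.63	alpha-D-ribose 1-methylphosphonate 5-triphosphate diphosphatase	P
2.7.4.23	ribose 1,5-bisphosphate phosphokinase	P
2.7.8.37	alpha-D-ribose 1-methylphosphonate 5-triphosphate synthase	P
3.11.1.1	phosphonoacetaldehyde hydrolase	P
4.7.1.1	alpha-D-ribose 1-methylphosphonate 5-phosphate C-P-lyase	P
3.1.1.3	triacylglycerol lipase	P
2.7.13.3	histidine kinase (PhoR-type)	P
1.1.5.2	quinoprotein glucose dehydrogenase	P
3.1.3.5	5'-nucleotidase	P
2.7.4.1	polyphosphate kinase	P
3.1.4.16	2',3'-cyclic-nucleotide 2'-phosphodiesterase	P
2.6.1.37	2-aminoethylphosphonate transaminase	P
3.11.1.2	phosphonoacetate hydrolase	P
3.11.1.3	phosphonopyruvate hydrolase	P
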