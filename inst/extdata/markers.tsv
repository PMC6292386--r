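marker_id	function_category	note
TIGR1282	nitrogen fixation	nifD, Mo-Fe nitrogenase alpha subunit
TIGR1286	nitrogen fixation	nifK, Mo-Fe nitrogenase beta subunit
TIGR1287	nitrogen fixation	nifH, nitrogenase iron protein
TIGR2064	dissimilatory sulfite reduction	dsrA
COG2221	dissimilatory sulfite reduction	dsrB-like
TIGR4529	sulfide oxidation	sqr, sulfide:quinone reductase
PF01266a	sulfide oxidation	FAD-dependent oxidoreductase family
TIGR4486	thiosulfate oxidation	soxB
TIGR4484	thiosulfate oxidation	soxA
TIGR3326	carbon fixation	rbcL, RuBisCO large subunit
PF00101	carbon fixation	rbcS, RuBisCO small subunit
TIGR2912	denitrification	nosZ, nitrous oxide reductase
COG3256	denitrification	norB, nitric oxide reductase
TIGR2175	denitrification	nirK, nitrite reductase
COG0804	urease	ureC, urease alpha subunit
PF00449	urease	urease beta subunit
PF02461	methanotrophy	pmoA, particulate methane monooxygenase
COG4993	methylotrophy	mxaF-like methanol dehydrogenase
TIGR2512	iron-only hydrogenase	hydA
COG3259	NiFe hydrogenase	group 3 NiFe hydrogenase large subunit
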