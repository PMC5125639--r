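# FeADH subfamily registry, v1 (CDD family cd08551 subfamilies)
# Columns are tab-separated. eukaryote_lineages: semicolon-separated lineage labels,
# empty when in_eukarya is FALSE. expected_res81: comma-separated one-letter residues
# with experimental/logo support; empty when unreported. res81_variable marks
# subfamilies in which position 81 is not conserved. expected_metal_site is one of
# tetrad_intact / asp242_substituted / variable. footnote records single exotic
# finds and dubious records that do not alter the presence flags.
cdd_id	abbreviation	activity_note	in_bacteria	in_eukarya	in_archaea	eukaryote_lineages	expected_res81	res81_variable	expected_metal_site	footnote
cd08176	LPO	Lactaldehyde:propanediol oxidoreductase; also 1,3-propanediol, methanol, ethanol and L-threonine dehydrogenases (NAD+)	TRUE	TRUE	TRUE	Euglenozoa;Heterolobosea;Fungi/Ascomycota;Viridiplantae/Chlorophyta	D	FALSE	tetrad_intact
cd08177	MAR	Maleylacetate reductase (NAD(P)H); 3-oxoadipate pathway; metal-independent	TRUE	TRUE	TRUE	Haptophyceae;Stramenopiles;Fungi/Ascomycota;Fungi/Basidiomycota	T,G	TRUE	asp242_substituted
cd08178	AAD-C	C-terminal alcohol dehydrogenase domain of bifunctional acetaldehyde-alcohol dehydrogenase (ADHE)	TRUE	TRUE	FALSE	Amoebozoa;Alveolata;Diplomonadida;Cryptophyta;Viridiplantae/Chlorophyta;Fungi/Ascomycota;Fungi/Neocallimastigomycota	D	FALSE	tetrad_intact
cd08179	NADPH-BDH	NADPH-dependent butanol dehydrogenase	TRUE	FALSE	TRUE		G	FALSE	tetrad_intact
cd08180	PDD	1,3-propanediol dehydrogenase (NAD+)	TRUE	FALSE	FALSE			FALSE	tetrad_intact
cd08181	PDD-like	Putative 1,3-propanediol dehydrogenase-like; binds NADP+	TRUE	TRUE	FALSE	Diplomonadida	G	FALSE	tetrad_intact
cd08182	HEPD	Hydroxyethylphosphonate dehydrogenase / phosphonoacetaldehyde reductase	TRUE	TRUE	TRUE	Stramenopiles		TRUE	variable	eukaryote presence: Nannochloropsis gaditana
cd08187	BDH	Butanol dehydrogenase / aldehyde reductase (NADP+)	TRUE	TRUE	FALSE	Stramenopiles;Amoebozoa;Parabasalidea	G	FALSE	tetrad_intact
cd08190	HOT	Hydroxyacid-oxoacid transhydrogenase (gene ADHFE1 in animals)	TRUE	TRUE	TRUE	Ichthyosporea;Apusozoa;Stramenopiles;Amoebozoa;Rhizaria;Fungi;Metazoa		FALSE	tetrad_intact
cd08193	HVD	5-hydroxyvalerate dehydrogenase	TRUE	TRUE	FALSE	Haptophyceae		FALSE	tetrad_intact	Viridiplantae/Tracheophyta record (Posidonia oceanica) considered dubious
cd08185	FeADH1	None characterized	TRUE	FALSE	TRUE			FALSE	tetrad_intact
cd08183	FeADH2	None characterized	TRUE	TRUE	TRUE	Alveolata;Stramenopiles;Rhodophyta;Viridiplantae/Chlorophyta		TRUE	asp242_substituted	archaea presence: Lokiarchaeum sp. GC14_75
cd08184	FeADH3	3-deoxy-alpha-D-manno-octulosonate 8-oxidase (KdnB)	TRUE	FALSE	FALSE			FALSE	tetrad_intact
cd08188	FeADH4	None characterized	TRUE	FALSE	TRUE			FALSE	tetrad_intact
cd08189	FeADH5	None characterized	TRUE	TRUE	FALSE	Euglenozoa		FALSE	tetrad_intact
cd08194	FeADH6	None characterized	TRUE	TRUE	TRUE	Alveolata;Haptophyceae;Rhizaria;Ichthyosporea;Fungi/Chytridiomycota		FALSE	tetrad_intact
cd08186	FeADH8	NADP+-dependent alcohol dehydrogenase (Thermococcus)	TRUE	TRUE	TRUE	Diplomonadida	G	TRUE	tetrad_intact
cd08192	FeADH7	Putative FeADH in linear alkylbenzenesulfonate degradation	TRUE	TRUE	TRUE	Haptophyceae;Stramenopiles		FALSE	tetrad_intact	archaea presence: Thaumarchaeota archaeon SCGC AB-539-E09
cd08191	HHD	6-hydroxyhexanoate dehydrogenase	TRUE	FALSE	FALSE			FALSE	tetrad_intact
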