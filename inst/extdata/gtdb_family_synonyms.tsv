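legacy_name	rank	gtdb_family	note
Methanosaetaceae	family	Methanotrichaceae	family renamed in GTDB r89
Methanosaeta	genus	Methanotrichaceae	genus renamed Methanothrix; family now Methanotrichaceae
Methanothrix	genus	Methanotrichaceae	type genus of Methanotrichaceae
Methanosaeta concilii	species	Methanotrichaceae	now Methanothrix soehngenii lineage
Methanothrix soehngenii	species	Methanotrichaceae	type species
Methanosarcina	genus	Methanosarcinaceae	.
Methanosarcina barkeri	species	Methanosarcinaceae	.
Methanosarcina mazei	species	Methanosarcinaceae	.
Methanomethylovorans	genus	Methanosarcinaceae	.
Methanolobus	genus	Methanosarcinaceae	.
Methanococcoides	genus	Methanosarcinaceae	.
Methanimicrococcus	genus	Methanosarcinaceae	.
Methanobacterium	genus	Methanobacteriaceae	.
Methanobacterium formicicum	species	Methanobacteriaceae	.
Methanobrevibacter	genus	Methanobacteriaceae	.
Methanosphaera	genus	Methanobacteriaceae	.
Methanothermobacter	genus	Methanothermobacteraceae	split from Methanobacteriaceae in GTDB
Methanoculleus	genus	Methanocullaceae	family split from Methanomicrobiaceae in GTDB r89
Methanoculleus bourgensis	species	Methanocullaceae	.
Methanofollis	genus	Methanofollaceae	family split from Methanomicrobiaceae in GTDB r89
Methanogenium	genus	Methanomicrobiaceae	.
Methanomicrobium	genus	Methanomicrobiaceae	.
Methanomicrobiaceae	family	Methanomicrobiaceae	narrowed in GTDB r89; genus-level records preferred
Methanospirillum	genus	Methanospirillaceae	.
Methanospirillum hungatei	species	Methanospirillaceae	.
Methanocorpusculum	genus	Methanocorpusculaceae	.
Methanolinea	genus	Methanoregulaceae	.
Methanoregula	genus	Methanoregulaceae	.
Methanosphaerula	genus	Methanoregulaceae	.
Methanomassiliicoccus	genus	Methanomassiliicoccaceae	.
Methanomethylophilus	genus	Methanomethylophilaceae	.
Candidatus Methanoplasma	genus	Methanomethylophilaceae	.
Methanoperedens	genus	Methanoperedenaceae	ANME-2d
Candidatus Methanoperedens	genus	Methanoperedenaceae	ANME-2d
Candidatus Methanoperedens nitroreducens	species	Methanoperedenaceae	.
Methylobacter	genus	Methylomonadaceae	Methylococcaceae genus reassigned in GTDB
Methylomonas	genus	Methylomonadaceae	.
Methylosarcina	genus	Methylomonadaceae	.
Methylomicrobium	genus	Methylomonadaceae	.
Methylococcus	genus	Methylococcaceae	.
Methylocaldum	genus	Methylococcaceae	.
Methylocystis	genus	Beijerinckiaceae	Methylocystaceae merged into Beijerinckiaceae in GTDB
Methylosinus	genus	Beijerinckiaceae	Methylocystaceae merged into Beijerinckiaceae in GTDB
Methylocystaceae	family	Beijerinckiaceae	merged into Beijerinckiaceae in GTDB
Methylocella	genus	Beijerinckiaceae	.
Methylacidiphilum	genus	Methylacidiphilaceae	.
Methylomirabilis	genus	Methylomirabilaceae	NC10 intra-aerobic methanotroph
Candidatus Methylomirabilis	genus	Methylomirabilaceae	NC10 intra-aerobic methanotroph
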