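token	role	substrate	description	aliases
mcrA	mcr_operon	.	methyl-coenzyme M reductase subunit alpha	mcr alpha
mcrB	mcr_operon	.	methyl-coenzyme M reductase subunit beta	.
mcrC	mcr_operon	.	methyl-coenzyme M reductase operon protein C	.
mcrD	mcr_operon	.	methyl-coenzyme M reductase operon protein D	.
mcrG	mcr_operon	.	methyl-coenzyme M reductase subunit gamma	.
pmoA	pmmo	.	particulate methane monooxygenase subunit A	.
pmoB	pmmo	.	particulate methane monooxygenase subunit B	.
pmoC	pmmo	.	particulate methane monooxygenase subunit C	.
mmoX	smmo	.	soluble methane monooxygenase hydroxylase alpha	.
mmoY	smmo	.	soluble methane monooxygenase hydroxylase beta	.
mmoZ	smmo	.	soluble methane monooxygenase hydroxylase gamma	.
mtsA	methylthiol_mtase	methylthiol	methylthiol:coenzyme M methyltransferase	.
mtaA	methylthiol_mtase	methylthiol	methylcobamide:coenzyme M methyltransferase	.
mtaB	methyl_mtase	methanol	methanol-corrinoid methyltransferase	methanol methyltransferase
mttB	methyl_mtase	trimethylamine	trimethylamine-corrinoid methyltransferase	trimethylamine methyltransferase
mtbB	methyl_mtase	dimethylamine	dimethylamine-corrinoid methyltransferase	dimethylamine methyltransferase
mtmB	methyl_mtase	methylamine	monomethylamine-corrinoid methyltransferase	methylamine methyltransferase
acs	acetate_activation	.	acetyl-CoA synthetase (AMP-forming)	Acetate pt 1,acetyl-CoA synthetase
pta	acetate_activation	.	phosphotransacetylase	acetate pt. 1,Acetate pt 3,phosphotransacetylase,acetyltransferase
ack	acetate_activation	.	acetate kinase	acetate pt. 2,Acetate pt 2,acetate kinase
nirK	nitrogen	.	copper-containing nitrite reductase (NO-forming)	.
nirS	nitrogen	.	cytochrome cd1 nitrite reductase (NO-forming)	.
narG	nitrogen	.	respiratory nitrate reductase alpha subunit	.
napA	nitrogen	.	periplasmic nitrate reductase	.
norB	nitrogen	.	nitric oxide reductase subunit B	.
nosZ	nitrogen	.	nitrous oxide reductase	.
ureC	misc	.	urease alpha subunit	.
phsA	sulfur	.	thiosulfate reductase molybdopterin subunit	thiosulfate reductase
ccoN	complex_iv_high	.	cbb3-type cytochrome c oxidase subunit I (high affinity)	high affinity complex IV
coxA	complex_iv_low	.	aa3-type cytochrome c oxidase subunit I (low affinity)	low affinity complex IV
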