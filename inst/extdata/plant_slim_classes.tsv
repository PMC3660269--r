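class	acronym	ontology	size	incomplete
Nucleotide binding	Ntbind	molecular_function	47	FALSE
Molecular function	MF	molecular_function	268	TRUE
DNA binding	DnaBind	molecular_function	107	FALSE
Transcription factor activity	TranscFact	molecular_function	307	FALSE
RNA binding	RnaBind	molecular_function	43	FALSE
Catalytic activity	Catal	molecular_function	334	TRUE
Receptor binding	RecBind	molecular_function	38	FALSE
Transporter activity	Transp	molecular_function	125	FALSE
Binding	Bind	molecular_function	173	TRUE
Protein binding	ProtBind	molecular_function	630	TRUE
Kinase activity	Kinase	molecular_function	68	FALSE
Transferase activity	Transf	molecular_function	173	TRUE
Hydrolase activity	Hydrol	molecular_function	190	FALSE
Enzyme regulator activity	EnzReg	molecular_function	41	FALSE
Cellular component	CC	cellular_component	234	TRUE
Extracellular region	ExtcellReg	cellular_component	109	FALSE
Cell wall	CellWall	cellular_component	77	FALSE
Intracellular	Intracell	cellular_component	167	TRUE
Nucleus	Nucleus	cellular_component	421	TRUE
Nucleoplasm	NuclPlasm	cellular_component	51	FALSE
Nucleolus	Nucleolus	cellular_component	84	FALSE
Cytoplasm	CitPlasm	cellular_component	168	TRUE
Mitochondrion	Mitochond	cellular_component	244	FALSE
Endosome	Endosome	cellular_component	58	FALSE
Vacuole	Vacuole	cellular_component	171	FALSE
Peroxisome	Peroxisome	cellular_component	32	FALSE
Endoplasmatic reticulum	EndRet	cellular_component	109	FALSE
Golgi apparatus	GolgiApp	cellular_component	100	FALSE
Cytosol	Cytosol	cellular_component	389	FALSE
Ribosome	Ribosome	cellular_component	98	FALSE
Plasma membrane	PlasmMb	cellular_component	353	FALSE
Plastid	Plastid	cellular_component	696	FALSE
Thylakoid	Thylk	cellular_component	147	FALSE
Membrane	Mb	cellular_component	472	TRUE
Reproduction	Reprod	biological_process	337	TRUE
Carbohydrate metabolic process	ChMet	biological_process	315	FALSE
Generation of precursor metabolites and energy	MetEn	biological_process	150	FALSE
Nucleobase, nucleoside, nucleotide, nucleic acid metabolic process	NaMet	biological_process	712	TRUE
DNA metabolic process	DnaMet	biological_process	191	FALSE
Translation	Transl	biological_process	82	FALSE
Protein modification process	ProtMod	biological_process	391	FALSE
Lipid metabolic process	LipMet	biological_process	324	FALSE
Transport	Transport	biological_process	531	FALSE
Response to stress	StressResp	biological_process	790	FALSE
Cell cycle	CellCycle	biological_process	234	FALSE
Cell communication	CellComm	biological_process	66	TRUE
Signal transduction	SigTransd	biological_process	305	FALSE
Cell-cell signaling	Cell-cell	biological_process	53	FALSE
Multicellular organismal development	MultDev	biological_process	490	TRUE
Biological process	BP	biological_process	879	TRUE
Metabolic process	Met	biological_process	279	TRUE
Cell death	CellDeath	biological_process	95	FALSE
Catabolic process	Catabolic	biological_process	479	FALSE
Biosynthetic process	Biosint	biological_process	1125	TRUE
Response to external stimulus	ExtResp	biological_process	65	TRUE
Tropism	Tropism	biological_process	36	FALSE
Response to biotic stimulus	BioResp	biological_process	275	FALSE
Response to abiotic stimulus	AbioResp	biological_process	642	FALSE
Anatomical structure morphogenesis	StrMorph	biological_process	366	FALSE
Response to endogenous stimulus	EndoResp	biological_process	332	FALSE
Embryonic development	EmbDev	biological_process	139	FALSE
Post-embryonic development	PostDev	biological_process	375	TRUE
Pollination	Poll	biological_process	43	FALSE
Flower development	FlowerDev	biological_process	228	FALSE
Cellular process	CP	biological_process	1486	TRUE
Response to extracellular stimulus	ExtcellResp	biological_process	59	FALSE
Photosyntesis	Photosyn	biological_process	102	FALSE
Cellular component organization	CellOrg	biological_process	757	FALSE
Cell growth	CellGrowth	biological_process	133	FALSE
Protein metabolic process	ProtMet	biological_process	187	TRUE
Cellular homeostasis	CellHom	biological_process	53	FALSE
Secondary metabolic process	SecMet	biological_process	164	FALSE
Cell differentiation	CellDiff	biological_process	267	FALSE
Growth	Growth	biological_process	64	TRUE
Regulation of gene expression, epigenetic	RGE	biological_process	103	FALSE
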