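gene	drug_id	drug_name	ttd_id	indication
PKLR	DB00119	Pyruvic acid	DAP000543	Dietary shortage
PKM2	DB00119	Pyruvic acid	DAP000543	Dietary shortage
MDH2	DB00157	NADH	DAP001291	Parkinson's disease
SDHB	DB00139	Succinic acid	DAP000545	Dietary shortage
PPARG	DB00159	Icosapent	DAP000969	Hyperglyceridemic
PPARG	DB00244	Mesalazine	DAP000729	Ulcerative colitis
PPARG	DB00328	Indomethacin	DAP000617	Patent ductus arteriosus
PPARG	DB00412	Rosiglitazone	DAP000271	Diabetes mellitus
PPARG	DB00731	Nateglinide	DAP000918	Diabetes mellitus
PPARG	DB00795	Sulfasalazine	DAP000153	Inflammatory bowel dieaseas and rheumatoid arthritis
PPARG	DB00912	Repaglinide	DAP000133	diabetes mellitus
PPARG	DB00966	Telmisartan	DAP000766	diabetes mellitus
PPARG	DB01014	Balsalazide	DAP000733	Inflammatory bowel disease
PPARG	DB01050	Ibuprofen	DAP000780	Pain
PPARG	DB01067	Glipizide	DAP000920	diabetes mellitus
PPARG	DB01132	Pioglitazone	DAP000272	diabetes mellitus
PPARG	DB01252	Mitiglinide	DAP000917	diabetes mellitus
PPARG	DB01393	Bezafibrate	DAP001182	hyperlipidaemia
EGFR	DB00072	Trastuzumab	DAP000391	breast cancer
EGFR	DB00281	Lidocaine	DAP000121	anesthetic
EGFR	DB00317	Gefitinib	DAP000657	cancers
EGFR	DB00530	Erlotinib	DAP001010	non-small cell lung cancer
EGFR	DB01259	Tykerb	DCL000344	bladder, head & neck, nsclc, brain cancer
JUN	DB00570	Vinblastine	DAP000785	cancers
JUN	DB01029	Irbesartan	DAP000364	hypertension
HSP90AA1	DB00615	Rifabutin	DAP000656	tuberculosis and mycobacterium avium complex (mac) disease
TYMS	DB00293	Raltitrexed	DAP000759	colon and rectum cancers
TYMS	DB00322	Floxuridine/5-fluorouracil	DAP001245	colorectal cancer
TYMS	DB00432	Trifluridine	DAP000760	viral infection
TYMS	DB00440	Trimethoprim	DAP000927	urinary tract infections
TYMS	DB00441	Gemcitabine	DAP001246	cancers
TYMS	DB00544	Fluorouracil	DAP000829	cancers
TYMS	DB00642	LY231514	DCL000320	non-squamous non-small cell lung cancer
TYMS	DB00650	Leucovorin/5-fluorouracil	DAP001244	colon cancer
TYMS	DB01101	Capecitabine	DAP000761	colorectal cancer
HDAC2	DB00227	Lovastatin	DAP000551	hypercholesterolemia
HDAC2	DB00277	Theophylline	DAP000002	chronic obstructive pulmonary disease
HDAC2	DB01223	Aminophylline	DAP000613	bronchial asthma
HDAC2	DB01303	Oxtriphylline	DAP000868	cough
HDAC2	DB02546	Vorinostat	DAP001082	cutaneous t-cell lymphoma
VCAM1	DB01136	Carvedilol	DAP000135	congestive heart failure
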