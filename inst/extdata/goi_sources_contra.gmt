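apoptosis_pathway	apoptosis signaling canonical pathway GOI, contralateral	ACIN1	BAX	KRAS	MAPK8
network_1	interaction network 1 GOI, contralateral	ACIN1	ACVR1C	CD44	DPYD	FGL2	MAPK8	MTDH	RAD23B	TTLL1
network_2	interaction network 2 GOI, contralateral	AURKAIP1	BTG2	CCND1	LCN2	MAFG	PIK3CD	PIK3R2	RND3	SETD8	SOX2	TRPM7	ZMYND11	ZNF148
network_3	interaction network 3 GOI, contralateral	AHI1	CDK11A	CDK19	DNAJB6	HSP90AA1	HSPB1	KLF13	LINGO1	MED1	PA2G4	PPP3CB	THRA	TUFM
network_4	interaction network 4 GOI, contralateral	EIF5B	ENTPD5	FOXO1	KRAS	MEF2A	PALLD	PRKAA2	PTK2B	RASSF4	Serbp
network_5	interaction network 5 GOI, contralateral	ATP2A2	ATP2B2	BAX	CDH13	GBX2	GSK3B	KCND2	MAFB	MFN1	NDUFAB1	PRKAA2
network_6	interaction network 6 GOI, contralateral	CCDC86	CCND2	CEBPD	GSK3B	PRLR	PSIP1	RSF1	SP1	SPP1	TIMP1
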