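apoptosis_pathway	apoptosis signaling canonical pathway GOI, ipsilateral	BCL2A1	CASP3	CASP7	CDK1	IKBKB	MAP4K4	MCL1	NFKB2	TNFRSF1A
network_1	interaction network 1 GOI, ipsilateral	CALB1	CDCA7L	CMIP	DAB2	FLNA	GCLM	GFAP	NFE2L2	PDLIM7
network_2	interaction network 2 GOI, ipsilateral	ANXA1	ATF3	BAG3	CCNA2	CDK1	CDKN1B	ETV5	FN1	LATS1	MCL1	MCM2	MCM8	MMS22L	NAA15	RAB35	SPIN1	TAGLN2	THOC2	TJP2	UNC5B
network_3	interaction network 3 GOI, ipsilateral	BCL11A	CCND1	CREB1	CREBBP	CSRNP1	DES	IKBKB	ITPR2	KLF6	KPNB1	MITF	NFIX	PTGR1	RAI14	RRM2	SENP2	SMARCA4	SUDS3	TBL1XR1	TGM2	THRA
network_4	interaction network 4 GOI, ipsilateral	ALB	BTG2	Ccl2	CCL3L3	CCL4	Ccl6	Ccl7	CD36	CEBPB	CREM	CX3CL1	CXCL3	Cxcl9	DUSP5	EGR2	FGF2	FGL2	FOSL1	HMOX1	IL1B	IL6R	ITGB2	KLF4	NEK6	PDE4B	PTGS2	SPP1	TLR4
network_5	interaction network 5 GOI, ipsilateral	ACSL5	CAMK2N1	CHSY1	ELAVL1	MAP4K4	MSI2	PTGER3	TCEB3	TMEM123	TRAF6	WFS1
network_6	interaction network 6 GOI, ipsilateral	ARL11	CAMK1G	CASP3	CISD2	CLN5	DNAJB6	DNAJB9	FGR	HCK	HSPA1A/HSPA1B	HSPA2	HSPA9	HSPB8	MDM2	PCDH15	PI4K2A	PRDM2	SGPL1	SNCA	SRPK2	TMEM109
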