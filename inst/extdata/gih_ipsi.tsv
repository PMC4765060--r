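gene	fold_change	tier
ATF3	12.027	primary
CCND1	2.152	primary
CEBPB	3.366	primary
CREB1	2.666	primary
CREBBP	2.421	primary
MDM2	2.01	primary
NFE2L2	2.452	primary
SMARCA4	2.521	primary
STAT3	4.219	primary
CDK1	2.105	primary
CSNK2A1	2.992	primary
EGFR	6.773	primary
GSK3B	-2.733	primary
CD44	15.558	primary
FN1	3.97	primary
TRAF6	2.163	primary
CASP3	2.535	primary
ELAVL1	3.275	primary
CEBPD	11.271	secondary
CREM	2.165	secondary
EGR2	2.271	secondary
FOSL1	5.875	secondary
KLF4	2.057	secondary
MITF	4.755	secondary
TCF4	-2.216	secondary
HSPA1A/HSPA1B	3.137	secondary
MCM2	2.57	secondary
PTGS2	3.106	secondary
IL1B	5.166	secondary
SPP1	37.905	secondary
CDKN1B	3.732	secondary
IKBKB	2.127	secondary
KPNB1	3.173	secondary
MCL1	3.25	secondary
THRA	-2.799	secondary
CASP7	2.579	secondary
BAG3	4.045	secondary
CCNA2	2.633	secondary
GFAP	3.011	secondary
HSPA9	2.666	secondary
HSPB1	46.922	secondary
SNCA	-2.169	secondary
ACSL5	-2.361	peripheral
ANXA1	3.535	peripheral
CHSY1	2.873	peripheral
CP	27.838	peripheral
EHD4	2.361	peripheral
GCLM	2.019	peripheral
HMOX1	9.778	peripheral
MCM8	2.027	peripheral
MX1	28.177	peripheral
PDE4B	5.602	peripheral
RAB35	2.086	peripheral
RRM2	3.34	peripheral
SDC1	13.681	peripheral
SETD8	2.029	peripheral
SGPL1	3.108	peripheral
SRXN1	6.306	peripheral
TGM2	3.574	peripheral
TOP2A	2.26	peripheral
BCL11A	-2.38	peripheral
BTG2	-2.22	peripheral
CCAR1	-2.943	peripheral
CSRNP1	2.821	peripheral
DEK	-3.006	peripheral
DNAJB6	-4.383	peripheral
ETV5	-2.163	peripheral
KLF13	-2.006	peripheral
KLF6	6.003	peripheral
NAA15	3.605	peripheral
NFIX	-2.548	peripheral
NFKB2	2.768	peripheral
PA2G4	-2.702	peripheral
PRDM2	3.677	peripheral
TBL1XR1	2.587	peripheral
TCEB3	3.053	peripheral
CAMK1G	-2.271	peripheral
CAMK2N1	-11.813	peripheral
CARD11	7.343	peripheral
CDK11A	-4.29	peripheral
FGR	3.915	peripheral
HCK	3.887	peripheral
HSPB8	4.112	peripheral
LATS1	2.003	peripheral
MAP4K4	2.258	peripheral
NEK6	2.322	peripheral
SRPK2	-5.614	peripheral
TJP2	2.552	peripheral
Ccl2	195.455	peripheral
CCL3L3	5.269	peripheral
CCL4	2.162	peripheral
Ccl6	10.291	peripheral
Ccl7	124.78	peripheral
CXCL3	13.211	peripheral
Cxcl9	2.846	peripheral
TIMP1	38.486	peripheral
IL6R	2.315	peripheral
IL6ST	2.307	peripheral
ITGB2	2.675	peripheral
TLR4	2.699	peripheral
TNFRSF1A	3.555	peripheral
UNC5B	2.067	peripheral
ALB	-3.125	peripheral
LCN2	71.824	peripheral
RASA1	2.392	peripheral
TPR	2.212	peripheral
FGL2	16.793	peripheral
SENP2	2.051	peripheral
DUSP5	3.285	peripheral
PTPRF	-6.365	peripheral
EIF3C	-4.369	peripheral
EIF5B	-3.044	peripheral
FGF2	2.387	peripheral
KCND2	-2.792	peripheral
AHI1	2.243	peripheral
BCL2A1	3.055	peripheral
CALB1	-2.091	peripheral
CD68	4.365	peripheral
CDCA7L	2.648	peripheral
CDT1	3.098	peripheral
CISD2	-7.833	peripheral
CMIP	-3.778	peripheral
DAB2	3.053	peripheral
DES	2.857	peripheral
DNAJB9	2.128	peripheral
FLNA	3.45	peripheral
GADD45G	3.191	peripheral
HLA-A	9.296	peripheral
HSPA2	3.51	peripheral
LCP1	6.082	peripheral
LSP1	11.716	peripheral
MMS22L	2.918	peripheral
MSI2	2.288	peripheral
PDLIM7	4.695	peripheral
PHLDA1	5.129	peripheral
PMEPA1	2.682	peripheral
PSIP1	-2.663	peripheral
RDX	4.828	peripheral
SERPINA3	58.488	peripheral
SPIN1	2.178	peripheral
SUDS3	2.228	peripheral
TAGLN2	3.891	peripheral
THOC2	2.119	peripheral
TMEM109	2.106	peripheral
TMEM123	2.348	peripheral
CYP1B1	10.998	orphan
KIF3A	-5.083	orphan
PTGR1	2.258	orphan
RND3	2.864	orphan
WFS1	2.083	orphan
ITPR2	2.489	orphan
KCNN4	3.088	orphan
ATRX	2.091	orphan
RAI14	3.284	orphan
CX3CL1	-2.044	orphan
PTGER3	2.425	orphan
PI4K2A	2.96	orphan
CD36	5.08	orphan
ARL11	3.143	orphan
Brd4	-3.528	orphan
CLN5	2.041	orphan
Ctdspl	-7.271	orphan
KIFAP3	-2.281	orphan
Nos1ap	-2.698	orphan
PCDH15	2.147	orphan
RASSF4	4.289	orphan
Rbm25	-5.547	orphan
Slpi	82.908	orphan
Tpm3	2.592	orphan
TRIM54	-4.426	orphan
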