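gene	fold_change	tier
CCND1	-2.027	primary
MED1	-4.011	primary
SMARCA4	-7.712	primary
SOX2	-4.791	primary
SP1	-2.076	primary
STAT3	-3.771	primary
CSNK2A1	-2.75	primary
EGFR	2.374	primary
GSK3B	-6.635	primary
CD44	2.399	primary
HSP90AA1	-4.843	primary
FOXO1	-3.329	secondary
MEF2A	-6.31	secondary
NFIX	-8.112	secondary
TCF4	-4.625	secondary
MAPK8	2.102	secondary
PIK3R2	2.332	secondary
PTK2B	2.15	secondary
KRAS	-2.027	secondary
TOP2A	-2.406	secondary
ATP2A2	-2.607	secondary
BAX	-3.306	secondary
SPP1	2.37	secondary
THRA	-11.518	secondary
TUFM	-2.109	secondary
CCND2	-3.617	secondary
HSPB1	2.639	secondary
BTG2	-5.803	peripheral
CCAR1	-11.648	peripheral
CEBPD	2.037	peripheral
DEK	-7.352	peripheral
DNAJB6	5.614	peripheral
GBX2	2.59	peripheral
KLF6	2.865	peripheral
MAFG	-2.632	peripheral
MTDH	-2.544	peripheral
PA2G4	-5.783	peripheral
RSF1	-2.618	peripheral
TBL1XR1	-2.134	peripheral
ZMYND11	-2.211	peripheral
ZNF148	2.114	peripheral
ACIN1	-2.515	peripheral
CYP1B1	4.808	peripheral
DPYD	2.292	peripheral
MFN1	2.304	peripheral
MX1	7.326	peripheral
SETD8	-3.93	peripheral
TTLL1	2.284	peripheral
ACVR1C	-9.107	peripheral
CARD11	2.892	peripheral
CDK11A	-14.872	peripheral
CDK19	-2.191	peripheral
PIK3CD	-2.113	peripheral
PRKAA2	-2.546	peripheral
SRPK2	-23.589	peripheral
PPP3CB	2.1	peripheral
PTPRF	-20.492	peripheral
IL6ST	-3.283	peripheral
PRLR	-3.192	peripheral
LCN2	3.895	peripheral
RASA1	-2.105	peripheral
TIMP1	2.101	peripheral
EIF5B	-8.766	peripheral
AHI1	-2.897	peripheral
CDT1	-2.295	peripheral
CISD2	-19.012	peripheral
GADD45G	-2.384	peripheral
HLA-A	3.657	peripheral
LINGO1	-2.173	peripheral
MAFB	-2.018	peripheral
PHLDA1	2.16	peripheral
PMEPA1	-2.937	peripheral
PSIP1	2.113	peripheral
RAD23B	-2.217	peripheral
RASSF4	2.106	peripheral
RDX	-5.274	peripheral
Serbp1	-2.059	peripheral
SERPINA3	2.509	peripheral
AURKAIP1	-2.023	orphan
CP	8.477	orphan
EHD4	-2.056	orphan
ENTPD5	-2.055	orphan
KIF3A	-11.754	orphan
NDUFAB1	-2.028	orphan
PDE4B	2.359	orphan
RND3	-2.971	orphan
SDC1	2.566	orphan
SRXN1	2.402	orphan
ATRX	-5.964	orphan
KLF13	-4.582	orphan
NAA15	-3.751	orphan
KCND2	-7.585	orphan
KCNN4	-9.429	orphan
CAMK2N1	-23.824	orphan
TRPM7	2.226	orphan
ATP2B2	2.276	orphan
TPR	-2.728	orphan
FGL2	4.017	orphan
EIF3C	-9.072	orphan
Brd4	-15.202	orphan
CCDC86	-2.149	orphan
CD68	2.007	orphan
CDH13	-2.692	orphan
CMIP	-13.763	orphan
Ctdspl	-36.886	orphan
KIFAP3	-7.831	orphan
LCP1	2.799	orphan
LSP1	2.14	orphan
Nos1ap	-5.717	orphan
PALLD	-5.086	orphan
Rbm25	-16.213	orphan
Slpi	3.119	orphan
THOC2	-4.886	orphan
Tpm3	-2.715	orphan
TRIM54	-2.032	orphan
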