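protein	role
MESPA	hub
MESPB	hub
MSGN1	hub
EBF2	hub
NEUROD6	hub
NEUROD4	hub
NEUROD2	hub
NEUROD1	hub
NEUROG1	hub
NEUROG3	hub
NHLH1	hub
TCF21	hub
TCF12	hub
TCF4	hub
TFEB	hub
TFE3	hub
HES4	hub
HES5.1	hub
HES7.1	hub
HES1	hub
DLL1	hub
SIM1	hub
SIM2	hub
ID2	hub
ID3	hub
ID4	hub
MYF6	hub
MYF5	hub
MYOG	hub
MYOD1	hub
NOTCH1	hub
OLIG2	hub
OLIG3	hub
OLIG4	hub
LYL1	hub
HEY1	hub
HEY2	hub
TWIST1	hub
HAND1	hub
HAND2	hub
MEF2C	hub
MGC75596	hub
MLX	hub
MXI1	hub
MAX	hub
LMYC1	hub
MNT	hub
MYC	hub
PTF1A	hub
TAL1	hub
MSC	hub
TAL2	hub
ATOH1	hub
ATOH7	hub
ARNT	hub
ARNT2	hub
AHR1	hub
BHLHE40	hub
BHLHE41	hub
HIF1A	hub
VHL	hub
CLOCK	hub
EPAS1	hub
CARM1	hub
NCOA1	hub
NCOA2	hub
NCOA3	hub
SREBF2	hub
CARM1	predicted_partner
INSIG2	predicted_partner
MEF2C	predicted_partner
VHL	predicted_partner
INSIG1	predicted_partner
MGC75596	predicted_partner
NOTCH1	predicted_partner
DLL1	predicted_partner
SCAP	predicted_partner
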