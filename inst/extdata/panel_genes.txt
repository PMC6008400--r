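KRAS
MYB
NF1
SF3B1
AKT1
CBFB
CTCF
FOXA1
MDM2
MDM4
MLL2
MLL3
NCOR1
PIK3R1
PTEN
TBX3
AGTR2
ATR
BIRC6
BRAF
CDH1
CDKN1B
CSF1R
DDR1
ERBB2
GATA3
INSRR
JAK1
JAK2
KIT
LTK
LYN
MALAT1
MAP2K4
MAP3K1
MET
PDGFRA
PIK3CA
RB1
RUNX1
TP53
ESR1
SMG1
ERBB3
ERBB4
MTOR
FRG1B
MAP3K4
MLL
ATM
NOTCH4
PRKDC
PRLR
RELN
BRCA1
BRCA2
NCOA3
NCOR2
ARID1A
MED12
AKT2
AKT3
ARID1B
AURKA
CASP8
CAV1
FBXW7
FOXC1
FZD7
MAGI3
MAP3K13
MTAP
MYBL2
PIN1
PPP2R2A
RB1CC1
RERG
SMARCD1
TAB1
TAB2
TGFB1
TGFB2
XBP1
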