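TPX2
PRC1
FOXM1
CDK1
TGIF2
MCM2
H2AFZ
TOP2A
PCNA
UBE2C
MELK
TRIP13
NCAPD2
MCM7
RNASEH2A
RAD51AP1
KIF20A
CDC45
MAD2L1
ESPL1
CCNB2
FEN1
TTK
CCT5
RFC4
ATAD2
CKAP5
NXT1
PLK4
SLC2A1
HDGF
NXF1
ZWINT
PTTG1
CDC20
SMC4
PBK
CDKN3
CDC6
MCM10
ASPM
AURKA
AURKB
BUB1B
CENPA
CENPF
DLGAP5
ECT2
ERCC6L
GINS1
KIF2C
KIF11
NDC80
NUSAP1
OIP5
PLK1
RACGAP1
RAD21
RRM2
SPAG5
STIL
TACC3
TK1
TYMS
UBE2S
EXO1
KIF23
BIRC5
CEP55
MKI67
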