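# 51-gene ciliary training set (editable)
BBS1
BBS2
ARL6
BBS4
BBS5
MKKS
BBS7
TTC8
BBS9
BBS10
TRIM32
BBS12
MKS1
TMEM67
CC2D2A
CEP290
RPGRIP1L
TMEM216
B9D1
B9D2
TCTN1
TCTN2
TCTN3
TMEM138
TMEM231
TMEM237
CEP41
ALMS1
NPHP1
INVS
NPHP3
NPHP4
IQCB1
SDCCAG8
OFD1
AHI1
ARL13B
INPP5E
KIF7
IFT80
IFT88
IFT122
IFT140
IFT172
WDR19
WDR35
TTC21B
DYNC2H1
KIAA0586
PKHD1
CEP164
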