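# Crystallization additives never counted as ligands:
# cryoprotectants, detergents, buffers, precipitants, common solvent.
GOL
EDO
PEG
PG4
P6G
PE4
1PE
2PE
MPD
MRD
DMS
BME
MES
EPE
TRS
BTB
PIN
CIT
FLC
TLA
TAR
ACT
ACY
FMT
SO4
PO4
NO3
CO3
EOH
IPA
POL
GLC
BGC
SUC
TRE
MAL
FRU
XYL
NAG
MAN
BMA
LDA
LMT
DDM
OG
BOG
C8E
F09
SDS
SPD
SPM
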