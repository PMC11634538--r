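alias,canonical
AMEL,AMEL
AMELOGENIN,AMEL
AM,AMEL
CSF1PO,CSF1PO
CSF,CSF1PO
D1S1656,D1S1656
D2S441,D2S441
D2S1338,D2S1338
D3S1358,D3S1358
D5S818,D5S818
D6S1043,D6S1043
D7S820,D7S820
D8S1179,D8S1179
D10S1248,D10S1248
D12S391,D12S391
D13S317,D13S317
D16S539,D16S539
D18S51,D18S51
D19S433,D19S433
D21S11,D21S11
D22S1045,D22S1045
DXS101,DXS101
DYS391,DYS391
F13A01,F13A01
F13A1,F13A01
F13B,F13B
FESFPS,FESFPS
FES,FESFPS
FGA,FGA
LPL,LPL
PENTAC,PentaC
PENTAD,PentaD
PENTAE,PentaE
SE33,SE33
TH01,TH01
THO1,TH01
TPOX,TPOX
VWA,vWA
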