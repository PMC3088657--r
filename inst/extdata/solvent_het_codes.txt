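# water and common buffer / cryoprotectant components treated as solvent
HOH
DOD
WAT
GOL
EDO
PEG
PGE
PG4
MPD
DMS
ACT
FMT
CIT
TRS
EPE
MES
SO4
PO4
NO3
IMD
BME
ACY
EOH
IPA
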