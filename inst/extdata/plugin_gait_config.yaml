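# Default symmetric marker subset (Plug-in-Gait style, 28 markers) and
# relative segment-mass weights (Winter anthropometric proportions; each
# segment's mass split equally among that segment's retained markers).
# Weights sum to 1 over the 28 markers.
markers:
  - LFHD
  - RFHD
  - LBHD
  - RBHD
  - C7
  - CLAV
  - LSHO
  - RSHO
  - LELB
  - RELB
  - LWRA
  - RWRA
  - LASI
  - RASI
  - LPSI
  - RPSI
  - LTHI
  - RTHI
  - LKNE
  - RKNE
  - LTIB
  - RTIB
  - LANK
  - RANK
  - LHEE
  - RHEE
  - LTOE
  - RTOE
masses:
  LFHD: 0.02025   # head+neck 0.081 over 4 head markers
  RFHD: 0.02025
  LBHD: 0.02025
  RBHD: 0.02025
  C7:   0.062125  # trunk 0.497 over 8 trunk/pelvis/shoulder markers
  CLAV: 0.062125
  LSHO: 0.062125
  RSHO: 0.062125
  LASI: 0.062125
  RASI: 0.062125
  LPSI: 0.062125
  RPSI: 0.062125
  LELB: 0.028     # upper arm
  RELB: 0.028
  LWRA: 0.022     # forearm + hand
  RWRA: 0.022
  LTHI: 0.05      # thigh 0.100 over THI + KNE
  RTHI: 0.05
  LKNE: 0.05
  RKNE: 0.05
  LTIB: 0.02325   # shank 0.0465 over TIB + ANK
  RTIB: 0.02325
  LANK: 0.02325
  RANK: 0.02325
  LHEE: 0.00725   # foot 0.0145 over HEE + TOE
  RHEE: 0.00725
  LTOE: 0.00725
  RTOE: 0.00725
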