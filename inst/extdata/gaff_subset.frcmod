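GAFF-like subset for examples (bond k in kcal/mol/A^2, angles kcal/mol/rad^2)
MASS
ca 12.011
ha 1.008
nb 14.007

BOND
ca-ca  478.40   1.387
ca-ha  344.30   1.087
ca-nb  483.10   1.342

ANGLE
ca-ca-ca   67.18    119.97
ca-ca-ha   48.46    120.01
ca-ca-nb   68.80    117.22
ca-nb-ca   68.25    117.22

DIHE
ca-ca-ca-ca   1    3.625       180.0     2.0

IMPROPER

NONBON
  ca  1.9080  0.0860
  ha  1.4590  0.0150
  nb  1.8240  0.1700
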