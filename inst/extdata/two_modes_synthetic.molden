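[Molden Format]
[FREQ]
1650.000000
3650.000000
[FR-COORD]
O    0.0000000000   0.0000000000   0.0000000000
H    1.4300000000   1.1100000000   0.0000000000
H   -1.4300000000   1.1100000000   0.0000000000
[FR-NORM-COORD]
vibration 1
   0.0000000000  -0.0700000000   0.0000000000
   0.4100000000   0.5500000000   0.0000000000
  -0.4100000000   0.5500000000   0.0000000000
vibration 2
   0.0000000000   0.0500000000   0.0000000000
   0.5800000000  -0.4000000000   0.0000000000
  -0.5800000000  -0.4000000000   0.0000000000
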