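>donor_synthetic
A 0.33 0.60 0.08 0.01 0.01 0.58 0.71 0.06 0.17
C 0.36 0.13 0.04 0.01 0.01 0.02 0.08 0.05 0.19
G 0.18 0.14 0.81 0.97 0.01 0.38 0.12 0.82 0.19
T 0.13 0.13 0.07 0.01 0.97 0.02 0.09 0.07 0.45
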