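>sf1_synthetic
A 0.55 0.50 0.05 0.05 0.75 0.80 0.10
C 0.15 0.20 0.70 0.05 0.05 0.08 0.55
G 0.15 0.10 0.05 0.05 0.15 0.06 0.05
T 0.15 0.20 0.20 0.85 0.05 0.06 0.30
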