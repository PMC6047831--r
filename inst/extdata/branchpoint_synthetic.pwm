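>branchpoint_synthetic
A 0.20 0.55 0.03 0.02 0.68 0.93 0.03
C 0.20 0.15 0.75 0.03 0.03 0.03 0.60
G 0.15 0.10 0.02 0.03 0.27 0.02 0.02
T 0.45 0.20 0.20 0.92 0.02 0.02 0.35
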