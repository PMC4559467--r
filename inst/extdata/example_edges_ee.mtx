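%%MatrixMarket matrix coordinate real general
% three directed E-E edges of a 4-cell toy network (1-based indices)
4 4 3
1 2 1.5
2 3 0.25
4 1 2.0
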