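spot
1x1
2x1
3x1
4x1
5x1
1x2
2x2
3x2
4x2
5x2
1x3
2x3
3x3
4x3
5x3
1x4
2x4
3x4
4x4
5x4
1x5
2x5
3x5
4x5
5x5
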