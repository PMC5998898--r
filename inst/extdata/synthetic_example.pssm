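
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts

            A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   V   W   Y   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   V   W   Y
    1 M     1   2   3   4   5   6   7   8   9  10  11  12  13  14  15  16  17  18  19  20    0   0   0   0   0   0   0   0   0   0   0   0 100   0   0   0   0   0   0   0  0.50 0.10
    2 A     4  -1  -2  -2   0  -1  -1   0  -2  -1  -1  -1  -1  -2  -1   1   0   0  -3  -2   80   2   1   1   1   1   1   2   1   1   1   1   1   1   1   2   1   1   0   0  0.30 0.08
    3 G     0  -2   0  -1  -3  -2  -2   6  -2  -4  -4  -2  -3  -3  -2   0  -2  -3  -2  -3    2   1   2   1   0   1   1  85   1   0   0   1   0   0   1   2   1   0   0   0  0.45 0.12
    4 W    -3  -3  -4  -4  -2  -2  -3  -2  -2  -3  -2  -3  -1   1  -4  -3  -2  -3  11   2    0   0   0   0   0   0   0   0   0   0   0   0   0   1   0   0   0   0  98   1  0.80 0.15
    5 E    -1   0   0   2  -4   2   5  -2   0  -3  -3   1  -2  -3  -1   0  -1  -2  -3  -2    1   2   2   5   0   5  75   1   1   0   0   3   0   0   1   2   1   0   0   0  0.40 0.09
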