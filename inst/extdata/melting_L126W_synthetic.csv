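"temperature_C","ellipticity"
25,-20.094
30,-19.9725
35,-20.1253
40,-19.7607
45,-19.9505
50,-20.1201
55,-19.7923
60,-16.3521
65,-4.4813
70,-2.199
75,-1.783
80,-1.9423
85,-2.0933
90,-2.3322
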