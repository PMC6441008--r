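"temperature_C","ellipticity"
25,-20.1345
30,-19.9723
35,-19.7618
40,-20.1694
45,-19.9976
50,-19.0548
55,-7.1069
60,-2.2591
65,-1.7115
70,-2.0213
75,-1.9374
80,-1.8527
85,-2.0589
90,-2.156
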