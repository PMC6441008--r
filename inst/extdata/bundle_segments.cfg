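tm_order = TM1 TM2 TM3 TM4 TM5 TM6 TM7
fusion = T4L

[TM1]
range = A 1 20

[TM2]
range = A 21 40

[TM3]
range = A 41 60

[TM4]
range = A 61 80

[TM5]
range = A 81 100

[TM6]
range = A 101 120

[TM7]
range = A 121 140

[T4L]
range = A 141 180

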