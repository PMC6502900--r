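ph,ppm
4,2.648800
4.25,2.630603
4.5,2.612225
4.75,2.593684
5,2.575000
5.25,2.556191
5.5,2.537275
5.75,2.518272
6,2.499200
6.25,2.480078
6.5,2.460925
6.75,2.441759
7,2.422600
7.25,2.403466
7.5,2.384375
7.75,2.365347
8,2.346400
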