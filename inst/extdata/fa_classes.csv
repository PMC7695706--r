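fa,class
12:0,dietary
14:0,extended_dietary
14:1n-5,endogenous
15:0,extended_dietary
16:0,endogenous
16:1n-11,dietary
16:1n-9,endogenous
16:1n-7,extended_dietary
16:1n-5,endogenous
16:2n-4,dietary
16:3n-4,dietary
16:4n-1,dietary
17:0,extended_dietary
17:1,extended_dietary
18:0,endogenous
18:1n-11,dietary
18:1n-9,extended_dietary
18:1n-7,extended_dietary
18:2n-6,dietary
18:2n-4,dietary
18:3n-6,dietary
18:3n-3,dietary
18:4n-3,dietary
18:4n-1,dietary
20:0,endogenous
20:1n-11,dietary
20:1n-9,dietary
20:1n-7,dietary
20:2n-6,dietary
20:3n-3,dietary
20:4n-6,dietary
20:4n-3,dietary
20:5n-3,dietary
21:5n-3,dietary
22:0,endogenous
22:1n-11,dietary
22:1n-9,dietary
22:1n-7,dietary
22:4n-6,dietary
22:5n-6,dietary
22:5n-3,dietary
22:6n-3,dietary
24:1n-9,endogenous
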