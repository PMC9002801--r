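subject	sc_lo	sc_hi	sc_median	metabolic	vslope
A	110	120	110	100	110
B	110	130	120	110	110
C	90	90	90	90	100
D	70	80	80	80	120
E	80	90	80	80	125
F	120	130	130	120	120
G	120	130	130	120	140
H	90	100	90	90	125
I	100	110	110	90	95
J	120	130	130	120	120
K	100	115	105	100	150
L	120	130	125	100	110
M	100	115	105	NA	85
N	100	110	105	NA	117.5
O	90	100	95	NA	112.5
P	100	115	110	NA	137.5
Q	95	110	105	NA	97
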