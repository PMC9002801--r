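subject	sc_lo	sc_hi	sc_median	metabolic	vslope
A	110	120	110	100	110
B	110	120	120	110	110
C	100	110	110	90	100
D	90	100	100	80	120
E	100	110	100	80	125
F	100	110	110	120	120
G	80	90	90	120	140
H	60	100	70	90	125
I	70	80	70	90	95
J	100	110	110	120	120
K	70	80	70	100	150
L	50	65	55	100	110
M	60	75	65	NA	85
N	20	20	20	NA	117.5
O	75	85	80	NA	112.5
P	70	80	75	NA	137.5
Q	50	75	60	NA	97
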