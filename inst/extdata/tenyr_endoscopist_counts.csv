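endoscopist_id,n_procedures,n_adenoma_positive,n_advanced_adenoma_positive,n_ssl_positive,n_advanced_ssl_positive,mean_interval_years
A,3060,1112,94,58,8,8.9
B,981,343,36,8,0,9.0
C,3553,1447,129,91,21,8.8
D,2765,1109,92,83,17,8.8
E,1174,469,46,18,3,8.9
F,1258,338,39,21,1,9.2
G,679,301,12,40,11,8.6
H,1165,505,83,21,4,8.4
I,1615,264,30,6,0,9.5
J,2091,917,43,92,12,8.7
K,1876,1055,58,124,16,8.2
L,3284,1739,73,144,14,8.4
M,3437,1510,116,132,3,8.6
N,3799,1708,119,130,13,8.6
O,647,292,14,14,1,8.8
P,1707,844,74,87,16,8.4
Q,2964,1435,106,137,16,8.5
R,3209,1235,108,99,12,8.8
S,2168,816,52,61,8,8.9
T,3834,1633,119,152,23,8.7
U,3935,1324,127,68,9,9.1
V,1936,1014,114,104,17,8.2
W,643,268,33,4,0,8.8
X,1469,680,65,73,16,8.5
Y,1313,551,56,39,7,8.7
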