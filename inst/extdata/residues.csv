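aa,residue_mass,volume_A3,dndc
A,71.0788,88.6,0.167
R,156.1875,173.4,0.206
N,114.1038,114.1,0.192
D,115.0886,111.1,0.197
C,103.1388,108.5,0.206
Q,128.1307,143.8,0.186
E,129.1155,138.4,0.183
G,57.0519,60.1,0.175
H,137.1411,153.2,0.219
I,113.1594,166.7,0.179
L,113.1594,166.7,0.173
K,128.1741,168.6,0.181
M,131.1926,162.9,0.204
F,147.1766,189.9,0.244
P,97.1167,112.7,0.165
S,87.0782,89.0,0.170
T,101.1051,116.1,0.172
W,186.2132,227.8,0.277
Y,163.1760,193.6,0.240
V,99.1326,140.0,0.172
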