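farm_id,cohens_d,p_tukey
A,1.4,ns
B,0.7,ns
C,0.3,ns
D,1.2,<0.001
E,1.5,<0.001
F,0.7,ns
G,0.4,ns
H,0.7,ns
I,0.8,ns
J,1.4,<0.001
K,1.4,<0.001
L,0.4,ns
M,0.6,ns
N,0.2,ns
O,0.7,<0.05
P,0.2,ns
Q,1.1,<0.001
R,0.7,ns
S,0.7,ns
T,0.6,ns
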