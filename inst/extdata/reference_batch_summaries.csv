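farm_id,batch_id,n,mean,sd
A,1,24,4.9,1.6
A,2,24,13.7,6.1
B,1,24,4.8,3.1
B,2,24,6.5,1.7
C,1,24,35.9,25.7
C,2,24,42.5,15.2
D,1,24,13.6,8.3
D,2,24,34.0,18.0
E,1,24,13.7,3.7
E,2,24,54.5,24.1
F,1,24,24.5,6.0
F,2,24,32.0,13.2
G,1,24,15.6,4.7
G,2,24,13.8,3.7
H,1,24,17.6,5.5
H,2,24,25.0,14.3
I,1,24,20.3,3.6
I,2,24,32.6,21.1
J,1,24,36.5,9.7
J,2,24,18.4,7.5
K,1,24,11.3,3.6
K,2,24,29.6,11.8
L,1,24,30.2,9.1
L,2,24,26.5,8.8
M,1,24,29.7,7.1
M,2,24,24.6,10.4
N,1,24,26.9,12.6
N,2,24,28.6,6.0
O,1,24,29.5,8.8
O,2,24,43.8,24.5
P,1,24,31.8,13.7
P,2,24,29.2,15.1
Q,1,24,37.1,21.2
Q,2,24,16.6,4.8
R,1,24,21.3,12.4
R,2,24,29.4,9.9
S,1,24,27.2,11.8
S,2,24,37.4,15.0
T,1,24,25.0,9.0
T,2,24,33.9,12.9
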