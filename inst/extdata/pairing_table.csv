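res_a,res_aprime,energy,source
I,I,-4.00,placeholder-ordinal
I,L,-3.60,placeholder-ordinal
I,V,-3.40,placeholder-ordinal
I,A,-2.60,placeholder-ordinal
I,S,-1.90,placeholder-ordinal
I,T,-1.60,placeholder-ordinal
I,N,-1.10,placeholder-ordinal
I,Q,-1.00,placeholder-ordinal
I,E,-0.80,placeholder-ordinal
I,K,-0.75,placeholder-ordinal
L,L,-3.30,placeholder-ordinal
L,V,-3.10,placeholder-ordinal
L,A,-2.40,placeholder-ordinal
L,S,-1.40,placeholder-ordinal
L,T,-1.30,placeholder-ordinal
L,N,-0.90,placeholder-ordinal
L,Q,-0.85,placeholder-ordinal
L,E,-0.70,placeholder-ordinal
L,K,-0.65,placeholder-ordinal
V,V,-2.90,placeholder-ordinal
V,A,-2.20,placeholder-ordinal
V,S,-1.30,placeholder-ordinal
V,T,-1.20,placeholder-ordinal
V,N,-0.85,placeholder-ordinal
V,Q,-0.80,placeholder-ordinal
V,E,-0.60,placeholder-ordinal
V,K,-0.55,placeholder-ordinal
A,A,-1.80,placeholder-ordinal
A,S,-1.00,placeholder-ordinal
A,T,-0.95,placeholder-ordinal
A,N,-0.70,placeholder-ordinal
A,Q,-0.65,placeholder-ordinal
A,E,-0.50,placeholder-ordinal
A,K,-0.45,placeholder-ordinal
S,S,-1.30,placeholder-ordinal
S,T,-0.90,placeholder-ordinal
S,N,-0.80,placeholder-ordinal
S,Q,-0.70,placeholder-ordinal
S,E,-0.55,placeholder-ordinal
S,K,-0.50,placeholder-ordinal
T,T,-0.85,placeholder-ordinal
T,N,-0.75,placeholder-ordinal
T,Q,-0.70,placeholder-ordinal
T,E,-0.50,placeholder-ordinal
T,K,-0.45,placeholder-ordinal
N,N,-1.50,placeholder-ordinal
N,Q,-0.60,placeholder-ordinal
N,E,-0.40,placeholder-ordinal
N,K,-0.35,placeholder-ordinal
Q,Q,-0.55,placeholder-ordinal
Q,E,-0.35,placeholder-ordinal
Q,K,-0.30,placeholder-ordinal
E,E,-0.10,placeholder-ordinal
E,K,-0.45,placeholder-ordinal
K,K,-0.05,placeholder-ordinal
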