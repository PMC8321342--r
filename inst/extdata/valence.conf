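# Maximum bond-order sum per element (valence budget used by the
# feasibility check and hydrogen balancing). Override with your own file
# via valence_model(path = ...).
H  1
C  4
N  3
O  2
S  6
P  5
F  1
Cl 1
Br 1
I  1
B  3
Si 4
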