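# Equilibrium single-bond lengths in Angstrom, from summed covalent
# radii. Pairs are unordered. "k" sets the global harmonic force
# constant (energy / Angstrom^2).
k 1.0
C  C  1.54
C  H  1.09
H  H  0.74
O  H  0.96
C  O  1.43
O  O  1.48
N  H  1.01
C  N  1.47
N  N  1.45
N  O  1.40
S  H  1.34
C  S  1.82
S  S  2.05
P  H  1.42
C  P  1.84
C  F  1.35
C  Cl 1.77
C  Br 1.94
C  I  2.14
Si H  1.48
C  Si 1.85
B  H  1.19
C  B  1.55
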