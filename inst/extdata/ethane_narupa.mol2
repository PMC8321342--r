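@<TRIPOS>MOLECULE
narupa builder molecule
8 7 0 0 0
SMALL
GASTEIGER
@<TRIPOS>ATOM
1 C1 -6,165 0,925 -6,713 C.3 1 N1
2 C2 -5,555 0,741 -5,798 C.3 1 N1
3 H1 -7,070 0,516 -6,599 H 1 N1
4 H2 -5,711 0,516 -7,504 H 1 N1
5 H3 -6,261 1,910 -6,857 H 1 N1
6 H4 -4,737 0,221 -6,042 H 1 N1
7 H5 -6,096 0,221 -5,137 H 1 N1
8 H6 -5,287 1,615 -5,394 H 1 N1
@<TRIPOS>BOND
1 2 1 1
2 8 2 1
3 7 2 1
4 6 2 1
5 5 1 1
6 4 1 1
7 3 11
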