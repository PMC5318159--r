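anticodon	copies
GAA	1
TAA	5
GAG	1
TAG	1
GAT	2
TAT	4
GAC	2
TAC	2
GGA	1
TGA	4
GGG	1
TGG	5
GGT	6
TGT	4
GGC	2
TGC	2
GTA	3
GTG	1
TTG	1
GTT	3
TTT	4
GTC	5
TTC	5
GCA	5
GCG	4
TCG	2
GCT	4
TCT	3
GCC	2
TCC	1
CCA	2
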