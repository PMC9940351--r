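codon	tai
AAA	0.4036
AAC	0.0916
AAG	0.7242
AAT	0.6748
ACA	0.2874
ACC	0.3351
ACG	0.6056
ACT	0.3668
AGA	0.6409
AGC	0.5685
AGG	0.8858
AGT	0.7215
ATA	0.7454
ATC	0.9351
ATG	0.4824
ATT	0.6108
CAA	0.8294
CAC	0.2629
CAG	0.4411
CAT	0.0867
CCA	0.7157
CCC	0.959
CCG	0.2527
CCT	0.678
CGA	0.9272
CGC	0.8059
CGG	0.1177
CGT	0.4199
CTA	0.4361
CTC	0.6764
CTG	0.4522
CTT	0.3549
GAA	0.2378
GAC	0.205
GAG	0.5471
GAT	0.9178
GCA	0.2464
GCC	0.8236
GCG	0.0692
GCT	0.9286
GGA	0.4632
GGC	0.47
GGG	0.7727
GGT	0.3663
GTA	0.4246
GTC	0.2716
GTG	0.118
GTT	0.9177
TAC	0.7831
TAT	0.1522
TCA	0.1253
TCC	0.4622
TCG	0.6958
TCT	0.7476
TGC	0.4799
TGG	0.7946
TGT	0.6958
TTA	0.5428
TTC	0.7063
TTG	0.6089
TTT	0.8239
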