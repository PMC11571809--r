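# synthetic codon stability coefficients (not experimental data)
# negative csc = suboptimal codon; Cys/His codons set suboptimal
codon	csc
AAA	-0.0741
AAC	-0.0353
AAG	-0.0156
AAT	-0.0882
ACA	-0.0206
ACC	0.0244
ACG	0.0396
ACT	-0.0203
AGA	-0.036
AGC	0.0392
AGG	0.0465
AGT	-0.0174
ATA	-0.0861
ATC	-0.048
ATG	-0.0307
ATT	-0.0676
CAA	-0.01
CAC	-0.0894
CAG	0.0257
CAT	-0.1409
CCA	0.0335
CCC	0.0683
CCG	0.0629
CCT	0.0166
CGA	0.0158
CGC	0.0691
CGG	0.0659
CGT	0.0129
CTA	-0.0284
CTC	0.0231
CTG	0.0121
CTT	-0.0332
GAA	-0.0286
GAC	0.0314
GAG	0.0243
GAT	-0.0314
GCA	0.0122
GCC	0.0762
GCG	0.0658
GCT	0.0215
GGA	0.0089
GGC	0.0819
GGG	0.0943
GGT	0.0029
GTA	-0.0246
GTC	0.0168
GTG	0.022
GTT	-0.042
TAC	-0.0473
TAT	-0.0751
TCA	-0.0382
TCC	0.0176
TCG	0.0278
TCT	-0.0343
TGC	-0.0981
TGG	0.0343
TGT	-0.1345
TTA	-0.0919
TTC	-0.0323
TTG	-0.0214
TTT	-0.0808
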