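#L=4
#model=lk
#K=1
#scheme=random
#seed=1
#note=synthetic
genotype	fitness
0000	2.3361857684794813
0001	1.8685031575150788
0010	2.7219234702643007
0011	2.2542408592998981
0100	2.2827809606678784
0101	2.9505070645827800
0110	2.6685186624526978
0111	3.3362447663675994
1000	2.2121893998701125
1001	1.7445067889057100
1010	2.4321086660493165
1011	1.9644260550849140
1100	2.0808152598328888
1101	2.7485413637477905
1110	2.3007345260120928
1111	2.9684606299269944
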