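name	adapter3	declared_rand5	declared_rand3
truseq	TGGAATTCTCGGGTGCCAAGG	0	0
nextflex	TGGAATTCTCGGGTGCCAAGG	4	4
nebnext	AGATCGGAAGAGCACACGTCT	0	0
qiaseq	AACTGTAGGCACCATCAAT	0	0
smarter_polya	AAAAAAAAAAAA	0	0
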