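name	targets	composition	max_count	methylation_class
ub	K	C4H6N2O2	2	FALSE
me	K	CH2	2	TRUE
me2	K	C2H4	2	FALSE
me3	K	C3H6	2	FALSE
ac	K	C2H2O	2	FALSE
ox	M	O	1	FALSE
ph	S,T,Y	HPO3	1	FALSE
prop	K,protein-nterm	C3H4O	2	FALSE
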