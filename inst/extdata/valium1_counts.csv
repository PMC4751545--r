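# Long-hairpin (VALIUM1) screen arm: per-genotype wing-score counts.
# Control: Luciferase hairpin. Categories s0-s5 = ordinal scores, B = blistered.
genotype,s0,s1,s2,s3,s4,s5,B
Luciferase,0,5,20,35,7,0,0
trx,0,0,1,9,2,0,1
Pc,0,0,2,9,14,0,1
ISWI,0,13,24,4,0,0,0
Rtf1,6,7,1,1,0,0,0
ash1,0,2,8,14,6,0,0
Bre1,1,2,6,5,1,0,18
Hp1c,0,0,7,25,5,0,0
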