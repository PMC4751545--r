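# Short-hairpin (VALIUM20) screen arm: per-genotype wing-score counts.
# Control: mCherry shRNA. Categories s0-s5 = ordinal scores, B = blistered.
# CAUTION: this table is internally inconsistent as printed. The Su(var)205
# row duplicates the mCherry control row (which cannot yield a significant
# rank test), and the published p-value column for the non-significant rows
# (0.492, 0.149, 0.291, 0.903) is not reproduced from these counts under the
# test variant that reproduces the long-hairpin arm exactly. Counts are kept
# verbatim; do not use the published column as a reference for this file.
genotype,s0,s1,s2,s3,s4,s5,B
mCherry,0,1,3,12,1,0,0
chd1,7,21,6,0,0,0,0
Su(var)205,0,1,3,12,1,0,0
Ino80,0,0,0,2,7,11,11
lds,0,0,0,10,6,4,4
Etl1,0,1,2,14,20,0,0
Marcal1,0,0,1,7,8,0,0
okra,0,2,7,7,4,0,0
chd3,0,0,6,15,6,0,0
Utx,0,0,4,6,0,0,1
Su(z)12,0,0,2,8,0,0,0
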