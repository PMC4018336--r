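# synthetic example of a pairwise type-I divergence coefficient table
# (coefficients chosen so the implied distances are additive on a star)
cluster_i	cluster_j	theta	se
DEFA1	DEFA4	0.7163	0.05
DEFA1	DEFA8	0.7534	0.05
DEFA4	DEFA8	0.5416	0.06
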