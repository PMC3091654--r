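# Published effect of MegaBLAST match reward (-r) and mismatch penalty
# (-q) on sensitivity and specificity, ovine BAC-end sequences vs the
# equine genome assembly. Percentages are of total reads (columns 1-2)
# and of positioned reads (column 3), printed at 2 decimals.
seed_type	pct_positioned	pct_tail_to_tail_of_total	pct_tail_to_tail_of_positioned	match_reward	mismatch_penalty
contiguous	76.78	32.36	42.15	1	-1
contiguous	77.57	31.91	41.14	2	-3
discontiguous	54.92	21.94	39.95	1	-1
discontiguous	51.17	22.64	44.24	2	-3
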