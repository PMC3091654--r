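# Published score-cutoff sweep: ovine BAC-end sequences aligned to the
# equine genome assembly with contiguous MegaBLAST (word size 8).
# X = reads with positions, o = reads in tail-to-tail clones,
# e = reads predicted to be in tail-to-tail clones; fp_rate and fn_rate
# are the printed (2-decimal) rates.
cutoff	X	o	e	fp_rate	fn_rate
8	292916	130358	230616	0.43	0.21
40	283315	130236	215746	0.40	0.24
45	263060	129806	186000	0.30	0.30
50	245983	128826	162636	0.21	0.34
55	236647	126698	150524	0.16	0.36
60	231047	125670	143484	0.12	0.38
65	225201	123140	136314	0.10	0.40
70	221398	121134	131750	0.08	0.40
100	200409	106368	107954	0.01	0.46
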