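sequence	mw	pi	ii	ai	gravy
MKWVTFISLLFLFSSAYS	2140.5405	8.3447	17.5667	108.3333	1.233333
GIGAVLKVLTTGLPALISWIKRKRQQ	2847.4471	12.0244	44.7308	135.0000	0.273077
ACDEFGHIKLMNPQRSTVWY	2395.7134	6.7845	84.7400	58.5000	-0.490000
KKKKKK	787.0491	10.6993	8.3333	0.0000	-3.900000
DDDDDD	708.5397	3.3213	8.3333	0.0000	-3.500000
MDAMKRGLCCVLLLCGAVFVSPS	2414.0068	7.7284	40.5565	114.3478	1.286957
LLQVVYLHSNNITKV	1741.0391	8.5982	44.6467	162.0000	0.540000
DPDSVTPTY	994.0098	3.5636	12.4778	32.2222	-1.055556
GPGPGGPGPG	748.7839	5.5250	21.3400	0.0000	-0.880000
WYAVRMSHHH	1323.4842	8.7685	76.6200	39.0000	-0.920000
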