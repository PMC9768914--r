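chrT	11000	11050	split	0	+
chrT	12000	12050	read	0	-
chrT	12000	12050	read	0	+
chrT	30000	30050	read	0	-
chrT	40000	40050	read	0	+
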