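EGFR	60	260	EGFR	exon1	complete_exon	1
ERBB2	60	260	ERBB2	exon1	complete_exon	1
MET	60	260	MET	exon1	complete_exon	1
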