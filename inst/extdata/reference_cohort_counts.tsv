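variable	level	n
total	all	2006
event	event	658
er_status	positive	1401
er_status	negative	605
her2_status	positive	457
her2_status	negative	1549
node_status	positive	806
node_status	negative	573
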