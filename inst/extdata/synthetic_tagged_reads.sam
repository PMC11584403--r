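@HD	VN:1.6	SO:coordinate
@SQ	SN:chr1	LN:1000
@CO	synthetic fixture: barcode/UMI-tagged reads around chr1:105 A>T
r1	0	chr1	101	60	10M	*	0	0	CCCCTCCCCC	IIIIIIIIII	CB:Z:CELL1	UB:Z:u1
r2	0	chr1	101	60	10M	*	0	0	CCCCTCCCCC	IIIIIIIIII	CB:Z:CELL1	UB:Z:u1
r3	0	chr1	103	60	10M	*	0	0	CCTCCCCCCC	IIIIIIIIII	CB:Z:CELL1	UB:Z:u2
r4	0	chr1	101	60	10M	*	0	0	CCCCACCCCC	IIIIIIIIII	CB:Z:CELL2	UB:Z:u3
r5	0	chr1	101	5	10M	*	0	0	CCCCTCCCCC	IIIIIIIIII	CB:Z:CELL2	UB:Z:u4
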