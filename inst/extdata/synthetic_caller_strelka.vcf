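##fileformat=VCFv4.2
##source=synthetic fixture (not real patient data)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##contig=<ID=chr1,length=1000000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NORMAL	TUMOR
chr1	10177	.	A	T	60	PASS	.	GT:AD:DP	0/0:38,0:38	0/1:35,15:50
chr1	20536	.	C	G	55	PASS	.	GT:AD:DP	0/0:41,1:42	0/1:30,20:50
chr1	30721	.	GTT	G	50	PASS	.	GT:AD:DP	0/0:36,0:36	0/1:28,12:40
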