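##fileformat=VCFv4.2
##contig=<ID=chr1,length=100000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	poolA	poolB
chr1	100	.	G	A,T	.	PASS	.	GT:AD:DP	0/1:10,10:25	0/0:20,2:25
chr1	200	.	C	T	.	PASS	.	GT:AD:DP	0/1:12,7:19	0/1:14,11:25
chr1	300	.	A	G	.	PASS	.	GT:AD:DP	./.:0,0:30	0/1:15,15:30
chr1	400	.	T	C	.	PASS	.	GT:AD:DP	0/0:249,1:250	0/0:249,1:250
chr1	500	.	A	C	.	PASS	.	GT:AD:DP	0/1:14,6:20	0/1:14,6:20
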