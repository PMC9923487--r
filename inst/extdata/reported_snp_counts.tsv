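quantity	count
biallelic_snps	22169780
blocksub_recovered_snps	1848
red_specific_snps	3622
yellow_specific_snps	3564
green_specific_snps	3240
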