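pool_id	site	color	n_individuals
poolA	S1	red	10
poolB	S1	green	10
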