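ligand_id	library_consensus_rank
83673143	286
155530661	1167
137796780	28
155563897	9
155552638	14
155557185	6
155511476	11
155538646	21
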