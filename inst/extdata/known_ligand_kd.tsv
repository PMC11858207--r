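ligand_id	kd_text
83673143	900 ± 108
155530661	230 ± 24
137796780	30 ± 4
155563897	20 ± 3
155552638	20 ± 4
155557185	8 ± 3
155511476	<5
155538646	<5
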