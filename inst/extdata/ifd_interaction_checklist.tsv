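ligand_id	kd_text	trp34_orientation	asp35_interaction	asp153_interaction	pocket_fill
83673143	900 ± 108	Flip-in	----	H-bond	Cl atom
155530661	230 ± 24	Flip-in	H-bond	----	Cl atom
137796780	30 ± 4	Flip-in	H-bond	H-bond	Cl atom
155563897	20 ± 3	Flip-in	H-bond	H-bond	Cl atom
155552638	20 ± 4	Flip-in	H-bond	H-bond	Cl atom
155557185	8 ± 3	Flip-in	H-bond	H-bond	Cl atom
155511476	<5	Flip-in	H-bond	H-bond	Cl atom
155538646	<5	Flip-in	H-bond	H-bond	Cl atom
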