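name	ligand_id	protein	kd_text
Isobavachin	193679	ApoE3	0.62
Isobavachin	193679	ApoE4	0.54
Isobavachin	193679	DNPH1	>100
Bavachin	14236566	ApoE3	59
Bavachin	14236566	ApoE4	64
Bavachin	14236566	DNPH1	No binding
Daidzein	5281708	ApoE3	>100
Daidzein	5281708	ApoE4	>100
Daidzein	5281708	DNPH1	>100
Genistein	5280961	ApoE3	>100
Genistein	5280961	ApoE4	>100
Genistein	5280961	DNPH1	>100
Glabrol	11596309	ApoE3	>100
Glabrol	11596309	ApoE4	77
Glabrol	11596309	DNPH1	>100
Idronoxil	219100	ApoE3	>100
Idronoxil	219100	ApoE4	>100
Idronoxil	219100	DNPH1	>100
Isoxanthohumol	513197	ApoE3	38
Isoxanthohumol	513197	ApoE4	40
Isoxanthohumol	513197	DNPH1	>100
Morusin	5281671	ApoE3	>100
Morusin	5281671	ApoE4	>100
Morusin	5281671	DNPH1	69
Mulberrin	5481958	ApoE3	>100
Mulberrin	5481958	ApoE4	>100
Mulberrin	5481958	DNPH1	>100
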