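ligand_id	1NFN	1BZ4	8CE0	8CDY	6NCN	6NCO
83673143	1027	1013	1029	993	733	853
155530661	328	490	185	204	519	572
137796780	527	565	242	298	65	45
155563897	426	208	186	628	60	18
155552638	444	400	660	664	109	76
155557185	471	652	519	505	61	25
155511476	470	651	827	774	111	95
155538646	594	611	659	744	116	148
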