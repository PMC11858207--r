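rank	ligand_id
1	53266
2	160487
3	5320382
4	114829
5	5282073
6	632135
7	193679
8	46886723
9	115067
10	5281601
11	5316844
12	92775
13	5280443
14	96539
15	5281617
16	5322078
17	10450045
18	198910
19	5319081
20	5320053
21	11601633
22	439246
23	5318980
24	5281698
25	72303
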