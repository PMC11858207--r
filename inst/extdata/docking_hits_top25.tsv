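rank	ligand_id
1	100781
2	161294
3	91510
4	193679
5	441805
6	11556558
7	94320
8	9974201
9	10114
10	71773126
11	163184367
12	14077830
13	9983614
14	11003773
15	64945
16	102501232
17	73347309
18	9548703
19	14463159
20	91471
21	5380976
22	114850
23	163005195
24	92097
25	151529
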