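Ligand: 193679
mode |   affinity | dist from best mode
     | (kcal/mol) | rmsd l.b.| rmsd u.b.
-----+------------+----------+----------
   1         -9.1      0.000      0.000
   2         -8.9      1.412      2.104
   3         -8.6      2.337      4.122
   4         -8.4      2.011      3.905
   5         -8.2      3.310      5.701
   6         -8.0      2.914      4.888
   7         -7.9      3.702      6.240
   8         -7.7      4.190      6.918
   9         -7.5      4.455      7.103
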