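# Published Ki values (uM) against MPS1, Aurora A and Aurora B with the
# ligand efficiencies as printed, "(-)" entries rendered as an empty
# le_printed and a ">" bound in ki_uM. Kis were derived from IC50s by the
# Cheng-Prusoff conversion at each assay's ATP conditions.
compound_id,kinase_id,ki_uM,le_printed
1,MPS1,>1000,
1,AURKA,361.0,0.59
1,AURKB,159.7,0.64
2,MPS1,94.7,0.39
2,AURKA,7.5,0.53
2,AURKB,3.2,0.53
3,MPS1,80.8,0.40
3,AURKA,393.9,0.30
3,AURKB,59.3,0.41
4,MPS1,236.4,0.33
4,AURKA,99.5,0.36
4,AURKB,102.7,0.36
5,MPS1,91.2,0.37
5,AURKA,184.7,0.31
5,AURKB,63.9,0.38
6,MPS1,30.2,0.34
6,AURKA,76.3,0.31
6,AURKB,41.7,0.33
7,MPS1,25.6,0.39
7,AURKA,21.3,0.40
7,AURKB,15.1,0.41
8,MPS1,11.0,0.37
8,AURKA,30.2,0.34
8,AURKB,12.0,0.37
9,MPS1,128.2,0.38
9,AURKA,66.9,0.41
9,AURKB,70.3,0.40
10,MPS1,269.3,0.35
10,AURKA,89.6,0.39
10,AURKB,18.7,0.46
11,MPS1,98.1,0.39
11,AURKA,125.2,0.38
11,AURKB,97.2,0.39
12,MPS1,367.3,0.26
12,AURKA,>100,
12,AURKB,12.9,0.37
13,MPS1,>100,
13,AURKA,>100,
13,AURKB,>100,
14,MPS1,>100,
14,AURKA,>100,
14,AURKB,>100,
15,MPS1,>100,
15,AURKA,>100,
15,AURKB,25.7,0.42
16,MPS1,5.4,0.33
16,AURKA,3.3,0.34
16,AURKB,41.0,0.27
17,MPS1,24.8,0.26
17,AURKA,>100,
17,AURKB,>100,
18,MPS1,30.1,0.24
18,AURKA,>100,
18,AURKB,32.9,0.23
19,MPS1,>100,
19,AURKA,>100,
19,AURKB,>100,
20,MPS1,>100,
20,AURKA,>100,
20,AURKB,>100,
21,MPS1,>100,
21,AURKA,>100,
21,AURKB,>100,
22,MPS1,4.8,0.25
22,AURKA,14.9,0.23
22,AURKB,5.5,0.25
23,MPS1,2.9,0.27
23,AURKA,2.6,0.27
23,AURKB,7.4,0.25
24,MPS1,3.2,0.29
24,AURKA,17.3,0.25
24,AURKB,3.6,0.28
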