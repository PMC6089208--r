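# Per-type allowed inter-cysteine spacings of the eight-cysteine motif
# C X(g1) C X(g2) CC X(g4) CXC X(g6) C X(g7) C
# Gaps count residues strictly between the flanking cysteines; the CC
# dyad (gap 0) and the CXC triplet (gap 1) are fixed and not listed.
"1":
  gpi: no
  g1: [9]
  g2: [13, 14, 16]
  g4: [19]
  g6: [19, 21, 22, 23, 24]
  g7: [13]
"2":
  gpi: no
  g1: [7]
  g2: [13]
  g4: [8]
  g6: [23]
  g7: [5, 6]
"C":
  gpi: no
  g1: [9]
  g2: [16]
  g4: [9]
  g6: [12]
  g7: [6]
"D":
  gpi: no
  g1: [9, 10, 14]
  g2: [14, 15, 16, 17, 19]
  g4: [9, 11, 12]
  g6: [19, 22, 24]
  g7: [6, 7, 8, 9, 10]
"E":
  gpi: no
  g1: [13]
  g2: [15]
  g4: [9]
  g6: [22]
  g7: [6]
"G":
  gpi: yes
  g1: [6, 9, 10]
  g2: [11, 13, 14, 16, 17, 18]
  g4: [12]
  g6: [23, 24, 25, 26, 29]
  g7: [5, 7, 8, 9]
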