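# Literature-typical marker panels for murine splenic B-cell gating.
# SYNTHETIC DEFAULTS for exercising the gating machinery; supply your own
# validated panels for real analyses.
subsets:
  immature_b: [CD24A, VPREB3]
  naive_b: [IGHD, FCER2A, SELL]
  activated_b: [CD69, CD83, NR4A1]
  gcbc: [AICDA, BCL6, S1PR2]
  mbc: [CCR6, ZEB2, CD38]
  pc: [PRDM1, XBP1, SDC1, IRF4]
  other: [CD3E, NKG7]
gc_zones:
  dz: [CXCR4, MKI67, AURKB]
  lz: [CD83, CD86, CXCR5]
pc_states:
  plasmablast: [MKI67, TIGIT]
  immature_pc: [TNFRSF13B, BCL2L11]
  mature_pc: [SLAMF7, CD93]
  apoptotic_pc: [CASP3, BAX]
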