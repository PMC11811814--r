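# Static pathway gene sets for modulation scoring (synthetic,
# literature-typical selections; pathway definitions are configuration,
# not code -- pin your own sets for real analyses).
bcr_signaling: [CD79A, CD79B, SYK, BTK, BLNK, PLCG2, LYN, PIK3CD, CARD11,
                NFKB1, NFATC1]
tlr4_signaling: [TLR4, CD14, LY96, MYD88, IRAK4, TRAF6, TICAM1, NFKB1,
                 MAPK14, JUN]
glycolysis: [HK1, HK2, GPI1, PFKL, ALDOA, GAPDH, PGK1, ENO1, PKM]
lactate_generation: [LDHA, LDHB, SLC16A1, SLC16A3]
tca_cycle: [CS, ACO2, IDH2, OGDH, SUCLA2, SDHA, FH1, MDH2]
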