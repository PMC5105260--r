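# Curated ring-system scaffold pool for the synthetic-library generator.
# Each entry is a pure framework (every atom has degree >= 2) whose first
# atom can carry one additional substituent.
c1ccccc1
C1CCCCC1
C1CCCC1
C1CCC1
C1CC1
C1CCCCCC1
c1ccncc1
c1ccnnc1
c1cncnc1
c1cnccn1
c1ccc2ccccc2c1
c1ccc2ncccc2c1
c1ccc2cnccc2c1
c1ccc2[nH]ccc2c1
c1ccc2occc2c1
c1ccc2sccc2c1
c1ccc2[nH]cnc2c1
c1ccc2nccnc2c1
c1ccc2c(c1)ccc3ccccc23
c1ccc2c(c1)Cc3ccccc23
c1ccc2c(c1)[nH]c3ccccc23
c1ccc2c(c1)oc3ccccc23
c1ccc2c(c1)sc3ccccc23
c1ccc2nc3ccccc3cc2c1
C1CCNCC1
C1CNCCN1
C1COCCN1
C1CCOC1
C1CCOCC1
C1CCNC1
C1CNC1
C1COC1
C1OCCO1
C1COCCO1
C1CSCCS1
C1CCSC1
C1CCSCC1
c1cocc1
c1ccsc1
c1cc[nH]c1
c1cnc[nH]1
c1cn[nH]c1
c1ocnc1
c1oncc1
c1scnc1
c1sncc1
c1nnc[nH]1
c1nc[nH]n1
C1CCC2CCCCC2C1
C1CCC2CCCC2C1
C1CC2CCC1C2
C1CC2CCC1CC2
C1CCC2(CC1)CCCCC2
C1CCC2(CC1)CCCC2
C1CN2CCC1CC2
c1ccc(-c2ccccc2)cc1
c1ccc(-c2ccncc2)cc1
c1ccc(-c2cccnc2)cc1
c1ccc(-c2ncccn2)cc1
c1ccc(-c2ccco2)cc1
c1ccc(-c2cccs2)cc1
c1ccc(Cc2ccccc2)cc1
c1ccc(CCc2ccccc2)cc1
c1ccc(CCCc2ccccc2)cc1
c1ccc(Oc2ccccc2)cc1
c1ccc(COc2ccccc2)cc1
c1ccc(Sc2ccccc2)cc1
c1ccc(Nc2ccccc2)cc1
c1ccc(CNc2ccccc2)cc1
c1ccc(CN2CCCCC2)cc1
C1CCN(CC1)c1ccccc1
c1ccc(Cc2ccncc2)cc1
c1ccc(Oc2ccncc2)cc1
c1ccc(CCc2ccncc2)cc1
c1ccc(Cc2ccc3ccccc3c2)cc1
c1ccc(-c2ccc3ccccc3c2)cc1
c1ccc(CC2CCCCC2)cc1
c1ccc(C2CCCCC2)cc1
c1ccc(OC2CCCCC2)cc1
c1ccc(CCN2CCCCC2)cc1
c1ccc(CCN2CCOCC2)cc1
c1ccc(CN2CCOCC2)cc1
C1CCC(CC2CCCCC2)CC1
C1CCC(C2CCCCC2)CC1
C1CCC(OC2CCCCC2)CC1
C1CCC(CC2CCNCC2)CC1
C1CCC(CC2CCOCC2)CC1
c1ccc(Cc2cccs2)cc1
c1ccc(Cc2ccco2)cc1
c1ccc(Cc2cc[nH]c2)cc1
c1ccc(-c2csc(-c3ccccc3)n2)cc1
c1ccc(CSc2ccccc2)cc1
c1ccc(CCOc2ccccc2)cc1
c1ccc(OCCOc2ccccc2)cc1
c1ccc(CCCCc2ccccc2)cc1
c1ccc(CC(c2ccccc2)c2ccccc2)cc1
C1CCC(C2CCCC2)CC1
C1CCC(C2CCC2)CC1
C1CC(C2CC2)C1
C1CC1C1CC1
C1CCC(CC2CCCC2)CC1
C1CCC(CCC2CCCCC2)CC1
c1cnc2[nH]ccc2c1
c1cnc2occc2c1
c1cnc2sccc2c1
c1ccc2c(c1)OCO2
c1ccc2c(c1)OCCO2
c1ccc2c(c1)CCC2
c1ccc2c(c1)CCCC2
c1ccc2c(c1)CCO2
c1ccc2c(c1)CCN2
c1ccc2c(c1)CNC2
c1ccc2c(c1)CCS2
c1ccc2c(c1)CCCN2
c1ccc2c(c1)CCCO2
c1ccc2c(c1)CCNC2
c1ccc2c(c1)CCOC2
c1cc2ccc3cccc4ccc(c1)c2c34
c1ccc2cc3ccccc3cc2c1
c1ccc2[nH]ncc2c1
c1ccc2nnccc2c1
c1nn[nH]n1
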