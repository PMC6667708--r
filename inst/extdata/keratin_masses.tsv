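mass	peptide_label	source
1066.0	keratin K1 tryptic	common-contaminant list
1179.6	keratin K1 tryptic	common-contaminant list
1234.7	keratin K10 tryptic	common-contaminant list
1277.7	keratin K9 tryptic	common-contaminant list
1300.5	keratin K1 tryptic	common-contaminant list
1320.6	keratin K1 tryptic	common-contaminant list
1365.6	keratin K10 tryptic	common-contaminant list
1383.7	keratin K2 tryptic	common-contaminant list
1475.8	keratin K10 tryptic	common-contaminant list
1638.9	keratin K10 tryptic	common-contaminant list
1707.8	keratin K1 tryptic	common-contaminant list
1716.9	keratin K2 tryptic	common-contaminant list
1838.9	keratin K1 tryptic	common-contaminant list
1994.0	keratin K1 tryptic	common-contaminant list
2384.0	keratin K1 tryptic	common-contaminant list
2510.3	keratin K2 tryptic	common-contaminant list
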