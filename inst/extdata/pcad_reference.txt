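WBN_GC_H_0.75
WBN_GC_L_1.00
WBN_GC_H_1.00
WBN_EN_L_0.50
WBN_EN_L_0.75
WBN_EN_H_0.75
WBN_EN_L_1.00
WBN_EN_H_1.00
WBN_LP_L_0.50
WBN_LP_H_0.50
WBN_LP_L_0.75
WBN_LP_H_0.75
WBN_LP_L_1.00
WBN_LP_H_1.00
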