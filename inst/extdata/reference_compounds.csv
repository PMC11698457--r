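var_id,mz,compound
Var31,585.145,neomangiferin
Var42,258.244,
Var43,342.171,lirioferine
Var44,328.155,norisocorydine
Var45,423.093,mangiferin
Var46,279.232,"15,16-dihydrotanshinone I"
Var47,433.114,apigenin-7-O-galactopyranoside
Var48,203.18,
Var49,328.155,norisocorydine
Var50,293.212,
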