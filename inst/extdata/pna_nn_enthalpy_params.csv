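term,neg_dH_kcal,se,wc_hbonds
AA,8.65,0.16,4
AT,8.28,0.32,4
TA,9.34,0.32,4
AG,10.64,0.27,5
GA,8.91,0.35,5
AC,8.90,0.19,5
CA,10.31,0.17,5
GG,12.32,0.19,6
GC,8.69,0.30,6
CG,11.71,0.34,6
Init,2.27,0.46,
T.GC,1.62,0.35,
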