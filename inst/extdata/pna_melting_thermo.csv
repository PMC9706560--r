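sequence,source,neg_dG_kcal,dG_se,neg_dH_kcal,dH_se,neg_dS_cal,dS_se
CGATCG,measured,13.64,0.25,58.78,4.09,151.42,12.89
AACGTT,measured,12.64,0.39,52.05,5.30,132.24,16.45
TAGCTA,measured,12.34,0.29,55.08,3.85,143.41,11.95
GTAGATCACT,literature,18.99,0.87,86.92,5.00,227.97,14.48
TGTTACGACT,literature,21.08,1.00,92.60,5.70,240.00,16.11
AGGTAACCAG,literature,18.76,0.60,83.30,2.80,216.60,7.40
AGTGAAGCAG,literature,19.02,0.82,82.15,4.56,211.85,12.86
TGATCTAC,literature,13.10,0.00,60.90,0.00,224.70,0.00
GTAGATCACTGT,literature,21.40,0.00,97.10,0.00,253.80,0.00
GTAGATCACTGTCAC,literature,26.40,0.00,117.10,0.00,304.30,0.00
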