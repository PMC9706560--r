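sequence,neg_dH_exp_kcal,exp_se,neg_dH_nn_kcal,anomalous
CGATCG,58.78,4.09,53.40,FALSE
AACGTT,52.05,5.30,49.07,FALSE
TAGCTA,55.08,3.85,50.91,FALSE
GTAGATCACT,86.92,5.00,87.09,FALSE
TGTTACGACT,92.60,5.70,85.24,TRUE
AGGTAACCAG,83.30,2.80,92.28,TRUE
AGTGAAGCAG,82.15,4.56,89.95,FALSE
TGATCTAC,60.90,0.00,67.55,FALSE
GTAGATCACTGT,97.10,0.00,106.30,FALSE
GTAGATCACTGTCAC,117.10,0.00,136.03,FALSE
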