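organ,method,mean_pct,sd_pct
gallbladder_wall,vsv,1.12,1.17
heart_wall,vsv,2.60,1.15
kidney,vsv,2.55,1.14
liver,vsv,1.86,0.71
lung,vsv,53.66,3.45
pancreas,vsv,1.71,1.09
spleen,vsv,1.55,0.97
stomach_wall,vsv,2.70,1.38
gallbladder_wall,cnn,1.18,1.20
heart_wall,cnn,1.14,1.09
kidney,cnn,0.67,0.57
liver,cnn,1.04,0.99
lung,cnn,1.30,1.15
pancreas,cnn,1.26,1.74
spleen,cnn,0.79,0.77
stomach_wall,cnn,1.35,1.19
gallbladder_wall,organ_based,22.27,22.28
heart_wall,organ_based,76.39,27.05
kidney,organ_based,3.86,3.29
liver,organ_based,19.01,31.90
lung,organ_based,23.43,33.86
pancreas,organ_based,1365.72,1186.49
spleen,organ_based,46.62,104.20
stomach_wall,organ_based,42.94,71.27
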