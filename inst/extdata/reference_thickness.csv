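specimen,thickness_um,thickness_sd_um,reported_reduction_pct,bin_0_250,bin_250_500,bin_500_750,bin_750_1000
healthy_molar,255.45,15.03,NA,2.34,3.10,2.14,1.21
demineralized_molar,150.30,10.02,41.1,2.09,2.21,1.24,0.77
carious_molar,100.20,6.68,60.8,1.24,0.74,0.41,0.11
demineralized_canine,140.28,9.35,45.1,1.10,1.21,0.99,0.65
demineralized_premolar,180.36,12.02,29.4,1.91,1.65,1.34,0.72
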