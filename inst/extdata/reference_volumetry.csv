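specimen,n_frames,residual_pixels,reported_volume_mm3
healthy_molar,500,2.13e7,28.72
demineralized_molar,500,1.31e7,17.70
carious_molar,500,0.91e7,12.26
demineralized_canine,500,1.28e7,17.20
demineralized_premolar,500,1.42e7,19.15
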