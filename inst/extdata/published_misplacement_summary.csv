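task,rom_correct_mean,rom_correct_sd,rom_medial_mean,rom_medial_sd,rom_lateral_mean,rom_lateral_sd,rmse_medial,rmse_lateral
hip_flexion,30.28,5.24,28.90,4.88,27.70,5.79,5.12,5.13
hip_extension,17.08,3.75,19.98,3.36,11.90,3.61,4.86,7.09
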