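task,imu_mean,imu_sd,mocap_mean,mocap_sd,abs_diff,accuracy_pct,rmse,mcid,mcid_exceeded,pcc,pcc_sig,ccc,ccc_sig
semi-squat,33.92,7.34,34.80,9.33,0.88,97.5,3.71,5,FALSE,0.95,TRUE,0.94,TRUE
hip_abduction,30.93,6.09,35.12,5.90,4.19,88.1,6.38,1.74,TRUE,0.82,TRUE,0.76,TRUE
hip_flexion,30.28,5.24,31.32,5.17,1.04,96.7,3.68,1.85,FALSE,0.86,TRUE,0.90,TRUE
hip_extension,17.08,3.75,23.40,4.26,6.32,73.0,8.47,3.78,TRUE,0.75,TRUE,0.43,FALSE
knee_extension,71.05,10.28,66.15,9.95,4.90,92.6,5.90,1.57,TRUE,0.95,TRUE,0.92,TRUE
trunk_flexion,40.15,8.36,30.15,5.50,10.00,66.8,14.55,8.07,TRUE,0.68,FALSE,0.52,FALSE
trunk_bending,26.53,5.33,30.10,6.06,3.57,88.1,4.49,3.24,TRUE,0.95,TRUE,0.83,TRUE
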