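scenario,rv_av_ml,closing_ml,leakage_ml,sv_av_ml,printed_rv_mv_ml,printed_rf_pct,printed_label
control,4.27,8.65,0.62,58.22,9.27,13.74,Mild
isolated_P3,4.34,8.54,3.36,55.18,11.90,17.74,Mild
isolated_P1,4.63,10.21,4.54,51.55,14.75,22.25,Mild
partial_P2P1,4.73,11.26,6.47,48.43,17.73,26.80,Mild
isolated_P2,4.61,11.86,12.46,41.94,24.32,36.70,Moderate
partial_P2P3,5.05,13.19,13.33,39.72,26.52,40.04,Moderate
total_P2P3,4.62,16.25,31.04,20.46,47.19,69.76,Severe
total_P2P1,4.72,17.08,34.45,16.16,51.53,76.13,Severe
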