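# normative CoP measures for healthy adult miniature Dachshunds in quiet standing
# per-dog means over five 10 s trials; force platform at 100 Hz, pressure mat at 60 Hz
# units: ranges cm, sway path cm, 95% ellipse area cm2
measure,mean_force_plate,sd_force_plate,mean_pressure_mat,sd_pressure_mat,pearson_r
ap_range,2.45,0.75,1.46,0.74,0.843
ml_range,3.45,0.98,2.76,1.07,0.816
ellipse_area_95,4.64,3.56,3.80,3.70,0.900
sway_path,816.38,186.61,146.78,44.89,0.490
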