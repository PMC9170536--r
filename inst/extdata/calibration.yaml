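# Duration-distance calibration used to invert waggle-run durations and
# to parameterize per-dance location clouds. These are round
# representative values of the published universal-calibration lineage;
# replace them with the constants your study uses.
intercept_s: 0.30        # seconds at zero distance
slope_s_per_m: 0.00135   # seconds of waggle per metre of distance
duration_sd_s: 0.15      # residual SD of duration at fixed distance (s)
angle_sd_deg: 15.0       # circular SD of the bearing error (degrees)
min_distance_m: 0        # floor applied when inverting short durations
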