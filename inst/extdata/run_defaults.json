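{
  "pixel_size_nm": 225,
  "frame_interval_s": 0.1,
  "window_s": 60,
  "dt_s": 4,
  "region_half": 20,
  "threshold": 0.4,
  "mbe_tolerance": 1e-4,
  "motility_window_min": 10,
  "motility_threshold_um": 0.45,
  "sampling_interval_s": 1,
  "log_level": "info"
}
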