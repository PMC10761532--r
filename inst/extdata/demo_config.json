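{
  "construct": {
    "name": "TTR-848",
    "unit_length": 848,
    "itr_junction_length": 130,
    "capacity": 4700
  },
  "capsid": {
    "vp1_mass": 81624,
    "vp2_mass": 66648,
    "vp3_mass": 59763,
    "vp1_count": 5,
    "vp2_count": 5,
    "vp3_count": 50
  },
  "mass_params": {
    "avg_nt_mass": 308.9,
    "counterion_factor": 1.04,
    "window_half_width": 0.025
  },
  "cdms": {
    "mixture": {
      "labels": ["empty", "1GOI-2ITR", "2GOI-3ITR", "3GOI-4ITR", "4GOI-5ITR", "5GOI-6ITR", "6GOI-7ITR"],
      "fractions": [0.798, 0.028, 0.0296, 0.0236, 0.0168, 0.0054, 0.0019]
    },
    "n_ions": 10000,
    "mode": "standard",
    "charge_mean": 155,
    "mz_cv": 0.002,
    "seed": 20231220
  },
  "gel": {
    "band_fractions": [5.2, 35.4, 24.1, 25.6, 6.2, 3.6],
    "band_sigma": 1.5,
    "noise_sigma": 0.002,
    "seed": 848
  },
  "output_dir": "aavterm_demo_out"
}
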