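{
  "species": "co",
  "anatomy": {
    "L_cm": 27.2,
    "z1_cm": 0.6,
    "A_c1_cm2": 217,
    "m": 2,
    "A_cA_cm2": 39444,
    "N_t": 480e6,
    "N_max": 263.3e6,
    "V_total_ml": 3700
  },
  "tissue_blood": {
    "A_M_aw_cm2": 9100,
    "dx_aw_um": 20,
    "A_M_A_cm2": 1.30e6,
    "dx_A_um": 0.6,
    "K_CO_cm2_min_atm": 2.15e-5,
    "COHb_pct": 0.56,
    "mcapO2Hb_pct": 97,
    "mcapPO2_mmHg": 90,
    "M": 220,
    "airway_blood_fraction": 0.1
  },
  "maneuver": {
    "ifr_ml_s": 121,
    "efr_ml_s": 121,
    "v_in_ml": 726,
    "v_ex_ml": 726,
    "hold_s": 0,
    "ambient_ppb": 130
  },
  "numerics": {
    "dz_cm": 0.1,
    "dt_s": 0.01,
    "axial_diffusion": true
  },
  "sensor": {
    "interval_s": 0.14,
    "noise_sd_ppb": 2,
    "flow_jitter_sd_ml_s": 0,
    "ramp_s": 0
  },
  "seed": 1
}
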