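{
  "comment": "Editable setpoints for the paper-like synthetic plasma-EV lipidome. Fractions are ground-truth relative abundances; nmr_class_fractions drive the 31P simulator, ms_species the LC-MS/MS simulator. PS is absent by construction.",
  "nmr_class_fractions": {
    "PC": 0.767,
    "SM": 0.203,
    "PE": 0.030
  },
  "ms_species": [
    {"class": "PC",  "chains": "16:0/18:1",  "fraction": 0.250},
    {"class": "PC",  "chains": "16:0/16:0",  "fraction": 0.110},
    {"class": "PC",  "chains": "18:0/18:1",  "fraction": 0.060},
    {"class": "PC",  "chains": "18:1/18:1",  "fraction": 0.045},
    {"class": "PC",  "chains": "14:0/16:0",  "fraction": 0.035},
    {"class": "LPC", "chains": "16:0",       "fraction": 0.100},
    {"class": "LPC", "chains": "18:1",       "fraction": 0.020},
    {"class": "SM",  "chains": "d18:1/16:0", "fraction": 0.120},
    {"class": "SM",  "chains": "d18:1/24:1", "fraction": 0.072},
    {"class": "SM",  "chains": "d18:1/18:0", "fraction": 0.048},
    {"class": "PI",  "chains": "16:0/18:1",  "fraction": 0.048},
    {"class": "PI",  "chains": "18:0/18:2",  "fraction": 0.032},
    {"class": "PE",  "chains": "16:0/18:1",  "fraction": 0.030},
    {"class": "PE",  "chains": "18:0/18:2",  "fraction": 0.030}
  ],
  "noise_params": {
    "ms_ppm_jitter": 5,
    "intensity_lognormal_sigma": 0.2,
    "nmr_replicate_sigma": 0.05,
    "nmr_snr": 100,
    "decoy_peak_rate": 0
  },
  "bbb_partition": {
    "passed_filter": 7.7,
    "passed_bbb": 1.3,
    "retained_apical": 88.4,
    "retained_cells": 2.6
  },
  "dls": {
    "mean_hd": 68.8,
    "pdi": 0.21
  }
}
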