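{
  "groups": {
    "STD": {
      "worn": {
        "alpha_o": 0.62,
        "alpha_a": 0.24,
        "all_trans": 0.72
      },
      "cup_sd": [0, 0, 0],
      "point_sd": [0, 0, 0],
      "mass_loss": [115, 0]
    }
  },
  "n_cups": 1,
  "n_points": 12,
  "a_ref": 20000,
  "baseline": [50, -10],
  "noise": {
    "type": "gaussian",
    "scale": 0,
    "floor": 100
  },
  "soak": [5, 0],
  "shapes": [
    {
      "center": 1065,
      "fwhm": 10,
      "gaussian_fraction": 0.5
    },
    {
      "center": 1085,
      "fwhm": 18,
      "gaussian_fraction": 0.5
    },
    {
      "center": 1130,
      "fwhm": 10,
      "gaussian_fraction": 0.5
    },
    {
      "center": 1295,
      "fwhm": 10,
      "gaussian_fraction": 0.5
    },
    {
      "center": 1305,
      "fwhm": 10,
      "gaussian_fraction": 0.5
    },
    {
      "center": 1416,
      "fwhm": 10,
      "gaussian_fraction": 0.5
    },
    {
      "center": 1441,
      "fwhm": 18,
      "gaussian_fraction": 0.5
    },
    {
      "center": 1461,
      "fwhm": 18,
      "gaussian_fraction": 0.5
    }
  ],
  "k_1065": 0.6,
  "k_bend": [1.2, 0.9],
  "twist_split": 0.55,
  "span": [1000, 1500],
  "step": 1,
  "seed": 7
}
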