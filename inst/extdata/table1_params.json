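{
  "24h": {
    "k_b": 0.0082,
    "v_G": 1.61,
    "v_S": 1.53,
    "k_GS": 0.64,
    "k_GP": 0.784,
    "k_SG": 0.598,
    "k_SP": 0.946,
    "k_PG": 0.335,
    "k_PS": 0.314,
    "beta": 0.19,
    "alpha": 1.564,
    "gamma": 0.602,
    "v_bar": 0.038,
    "D": 0.5039
  },
  "48h": {
    "k_b": 0.0016,
    "v_G": 1.62,
    "v_S": 1.08,
    "k_GS": 0.435,
    "k_GP": 0.933,
    "k_SG": 0.282,
    "k_SP": 1.251,
    "k_PG": 0.155,
    "k_PS": 0.235,
    "beta": 0.17,
    "alpha": 1.462,
    "gamma": 0.58,
    "v_bar": 0.027,
    "D": 0.2673
  },
  "96h": {
    "k_b": 0.0009,
    "v_G": 1.64,
    "v_S": 1.33,
    "k_GS": 0.799,
    "k_GP": 0.923,
    "k_SG": 0.575,
    "k_SP": 1.276,
    "k_PG": 0.116,
    "k_PS": 0.117,
    "beta": 0.19,
    "alpha": 1.359,
    "gamma": 0.678,
    "v_bar": 0.022,
    "D": 0.0216
  }
}
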