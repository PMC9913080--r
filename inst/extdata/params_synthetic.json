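{
  "provenance": "synthetic: package default parameter set, not estimated from data",
  "onset": {
    "nu": 0.051,
    "alpha": 1,
    "beta": 0.902,
    "mu": 0.00011
  },
  "growth": {
    "d0": 0.5,
    "v0": 0.0654498469497874,
    "shape": 1.4,
    "rate": 2,
    "eta": 0.00026
  },
  "nodal": {
    "size": 0.32,
    "coef": 0.008,
    "power": 0.5
  },
  "sensitivity": {
    "intercept": -4,
    "slope": 0.5
  },
  "survival": {
    "cure_intercept": 2.7,
    "cure_size": -0.06,
    "cure_slope_nodes": -0.3,
    "surv_shape": 1.2,
    "surv_log_scale": 2,
    "surv_size": -0.015,
    "surv_slope_nodes": -0.08
  }
}
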