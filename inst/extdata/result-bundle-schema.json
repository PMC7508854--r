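{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "tjumpmelt result bundle",
  "type": "object",
  "required": ["provenance", "truth", "melting", "kinetics", "mem"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "config_hash", "seed", "timestamp"]
    },
    "truth": {
      "type": "object",
      "required": ["dH0", "dS0", "dH_act_a", "dS_act_a",
                   "dH_act_d", "dS_act_d"]
    },
    "melting": {
      "type": "object",
      "required": ["dH0", "dS0", "residual_rms", "n_points", "T0_K", "T0_C"]
    },
    "kinetics": {
      "type": "object",
      "required": ["T_f_C", "lambda_obs", "k_a", "k_d", "assoc", "dissoc"]
    },
    "mem": {
      "type": "object",
      "required": ["mean_rate", "per_frequency", "chi2_per_point"]
    }
  }
}
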