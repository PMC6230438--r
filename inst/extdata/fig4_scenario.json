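{
  "comment": "Default two-limb steering scenario: five steps at each mean speed with a linearly increasing interlimb speed difference (ramp 0 -> dV_max).",
  "mean_speeds": [0.5, 1.0, 2.0],
  "n_steps": 5,
  "dV_max": 0.3,
  "W": 0.15
}
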