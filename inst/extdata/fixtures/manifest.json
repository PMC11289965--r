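{
  "shifted_dangle": {"model": "d1", "mfe": -2.9, "structure": "(((....)))."},
  "forced_outer": {"model": "d1", "constraint": "(.........)", "mfe": -2.4,
                   "structure": "(((.....)))"},
  "empty": {"model": "d2", "mfe": 0.0, "structure": ".........."}
}
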