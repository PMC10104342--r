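name: coin_toss
graph:
  p_heads:
    function: simdag::rand_uniform
    kwargs: {min: 0.0, max: 1.0}
  n_tosses:
    function: simdag::rand_int
    kwargs: {low: 10, high: 20}
  sequence:
    function: simdag::coin_toss_sequence
    kwargs: {p_heads: p_heads, n_tosses: n_tosses}
instructions:
  n_samples: 1000
  seed: 1
  output_dir: "."
  csv_name: coin_toss
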