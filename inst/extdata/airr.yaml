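# One sample per patient: disease state, age and experimental protocol
# condition the simulated immune receptor repertoire.
name: airr
graph:
  disease_state:
    function: simdag::rand_bernoulli
    kwargs: {p: 0.3}
  age:
    function: simdag::rand_uniform
    kwargs: {min: 0.0, max: 100.0}
  protocol:
    function: simdag::rand_categorical
    kwargs:
      labels: [baseline, amplicon]
  repertoire:
    function: simdag::airr_repertoire_node
    kwargs:
      disease_state: disease_state
      age: age
      protocol: protocol
      m: 500
      phi: 0.2
instructions:
  n_samples: 20
  seed: 1
  output_dir: "."
  csv_name: airr
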