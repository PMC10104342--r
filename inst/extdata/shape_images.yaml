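# Shapes overlaid on a black background: four scalar metadata variables
# control the probability of each shape appearing in the image.
name: shape_images
graph:
  V:
    function: simdag::rand_uniform
  C:
    function: simdag::rand_uniform
  R:
    function: simdag::rand_uniform
  H:
    function: simdag::rand_uniform
  image:
    function: simdag::shape_image
    kwargs: {v: V, c: C, r: R, h: H, size: 64}
instructions:
  n_samples: 50
  seed: 1
  output_dir: "."
  csv_name: shape_images
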