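Package: simdag
Title: Simulation of Data with Arbitrary Variable Types on Directed Acyclic Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declare a simulation model as a directed acyclic graph of named
    nodes, each generated by an arbitrary user function of its parents, and
    draw samples by forward sampling in topological order with native value
    passing, so variables may be scalars, strings, images or sets of
    sequences. Includes node kinds for sample-selection bias (rejection
    sampling), missing-data mechanisms and stratified output, a succinct
    YAML dialect with a command-line runner, CSV output with sidecar files
    for large values, and worked generators for coin-toss sequences, shape
    images and adaptive immune receptor repertoires.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
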