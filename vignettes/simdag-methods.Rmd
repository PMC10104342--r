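---
title: "simdag: model, semantics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{simdag: model, semantics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simdag)
```

## The simulation model

A `simdag` model is a directed acyclic graph over named nodes. Each node
carries an arbitrary generating function and a set of argument bindings:
literals are passed as constants, `node_ref()` bindings as the parent's
value for the current sample. Simulation is standard forward sampling: for
each sample, nodes are evaluated once each, in a topological order, and
parent values are handed over natively — no coercion to numeric, no
flattening. This is the structural-causal-model reading of a Bayesian
network; because the functions are unrestricted, there is no practical
distinction here between the probabilistic and the causal view, and the
same machinery simulates scalars, strings, matrices (images) or sets of
sequences.

Assumptions worth stating explicitly:

* **Per-sample evaluation.** Functions are called once per node per
  sample, never vectorised over the batch. A vectorised fast path would be
  an optimisation, not a semantic change; it is deliberately absent so
  user functions need no batch contract.
* **Randomness contract.** A single master seed (`sim_config(seed =)`)
  seeds R's global RNG stream once, at the start of the run. Node order
  and per-sample evaluation order are deterministic, so the entire run —
  including CSV bytes — is reproducible from the seed. Node functions are
  expected to draw only from the global stream; a function that manages
  its own RNG state forfeits reproducibility for its node.
* **Acyclicity is structural.** Cycles are rejected at build time (self
  loops included), before any function is called.

## Topological order and cycle detection

`build_graph()` derives the edge set from the `node_ref` bindings and
orders nodes with Kahn's algorithm. Ties — nodes simultaneously eligible —
are broken by declaration order. This makes the order, and hence CSV
column order and all output bytes, a pure function of the model. On
failure, one offending cycle is reconstructed by walking parent pointers
inside the irreducible subgraph and named in the error. The test suite
checks the cycle decision against an independent brute-force DFS,
exhaustively over all 4096 labelled 4-vertex digraphs and on random DAGs
up to 12 nodes.

## Special node kinds

**Selection** (at most one per graph). Selection could either filter a
fixed candidate pool or resample; `simdag` resamples: candidate
samples are drawn and the selection function evaluated per candidate;
candidates returning `FALSE` are discarded and drawing repeats until
`n_samples` are retained. This gives a predictable output size at the cost
of a run time inversely proportional to the acceptance probability, so a
rejection budget (`max_rejection_attempts`, default `10000 * n_samples`)
turns a near-zero acceptance probability into an error that reports the
acceptance rate observed so far. All nodes of a candidate are evaluated
before acceptance is known — simpler than restricting evaluation to the
selection node's ancestors, and semantically identical for the retained
samples. Restricting to a single selection node avoids defining the
composition order of several interacting rejection schemes.

**Missing** (`make_missing_node()`). A missing node references one
underlying standard node and one standard mask node returning `TRUE`
(mask) or `FALSE` (keep) per sample. Its value is the underlying value or
a dedicated missing sentinel. The sentinel is an R object distinct from
`NA` and `NaN`, so a *missing string* or a *missing image* is
representable; it renders as an empty CSV field. MCAR, MAR and MNAR are
obtained purely by wiring: a mask with no parents, a mask depending on
other observed nodes, or a mask depending on the underlying value itself.
A mask may not itself be a missing node (chained missingness is an
extension point, not supported); both the underlying and the masked column
are written when observed, and the underlying one is hidden by declaring
it `observed = FALSE`.

**Stratify** (at most one per graph). A labelling function assigns each
sample a scalar label; `stratify_rows()` partitions the table and
`write_sim_csv()` writes `<csv_name>_<label>.csv` per stratum. Labels are
sanitised to file-name-safe tokens (`[A-Za-z0-9._-]`, everything else
collapsed to `_`); a label that sanitises to the empty string is an error
rather than a silent file name.

**Plates.** Only flat plates are implemented: a node tagged
`plate = list(id, k)` is expanded at build time into `k` i.i.d. replicates
`name_1 .. name_k`. References between nodes sharing a plate id are
rewired replicate-wise (so a plated pair expands to `k` parallel chains);
plated nodes may reference shared unplated parents; an unplated node
referencing a plated one is rejected as ambiguous. Nested and intersecting
plates are out of scope. Mixture distributions need no dedicated node
kind: a categorical component-indicator node plus a standard node whose
function dispatches on it expresses any finite mixture.

**Hidden nodes.** `observed = FALSE` keeps a node out of the output while
it still feeds its children — latent-variable plumbing, nothing more.

## The YAML dialect

`parse_yaml()` and `emit_yaml()` implement a two-section document
(`graph:`, `instructions:`; full schema in `?parse_yaml`) equivalent to
the programmatic API: a YAML-defined run is byte-identical to the same
model built in code with the same seed, and `parse_yaml(emit_yaml(g, c))`
reconstructs the graph up to key order (functions must be
name-recoverable; anonymous functions are rejected at emit time).

Two open points were decided as follows:

* **Reference rule.** A `kwargs` string equal to a declared node name is a
  parent reference; any other string is a literal. A leading `=` forces
  literal interpretation of the remainder (`"=A"` is the string `"A"`),
  and `emit_yaml` inserts the escape automatically, keeping the round trip
  lossless. This keeps the succinct look of node references without making
  literals inexpressible.
* **Strictness.** Unknown keys are rejected by default and tolerated with
  a warning under `strict = FALSE` (CLI `--lax`): a typo in `kwargs` would
  otherwise silently turn a reference into a dangling literal.

Function names resolve in a fixed order — user registry
(`register_function()`), then `pkg::name`, then the search path — so ad
hoc functions work without packaging.

## Output formats

CSV is the primary sink (RFC-4180 quoting, UTF-8, header row, empty field
for missing). A CSV cell cannot hold an image or a repertoire natively,
so non-scalar values are serialised: up to 1024 items as an in-cell quoted
JSON literal, above that as per-sample sidecar files referenced by
relative path — tab-separated text for numeric matrices/tensors, FASTA
(records `seq1..seqm`) for sequence sets. Per-node serialisers
(`sim_config(serializers =)`) override the default, e.g. forcing FASTA
for repertoires of any size. Text sidecars were preferred to a binary
tensor format to keep every output inspectable with standard tools.
Numeric scalars are written with 15 significant digits, which round-trips
doubles through `read.csv` in practice.

## The example generators

The three shipped generators are first-class, tested library functions;
each graph also ships as a YAML document under `inst/extdata/`.

**Coin tosses** (`coin_toss_sequence()`): `n_tosses` i.i.d. draws, `H`
with probability `p_heads`, as one text string. Bounds (lengths 10–20,
probability uniform per sample) are fixed by the worked example the model
reproduces; out-of-range arguments are domain errors.

**Shape images** (`shape_image()`): a `size × size` (default 64) zero
grid; independently with probabilities `v`, `c`, `r`, `h` a Vertical bar,
Circle, Rectangle and Horizontal bar are overlaid at random positions and
sizes, pixels set to 1. The letter-to-shape mapping is this package's
convention, an initial-letter mnemonic.
The circle rasterisation rule is *pixel centre within the radius*, chosen
so a brute-force all-cells oracle can verify it exactly. The returned
object records each fired shape's geometry, making the generator testable
beyond summary statistics. Intensities are binary; overlapping shapes
simply union.

**Immune repertoires** (`airr_repertoire()`): per patient, `m` (default
500) DNA sequences with lengths uniform on 30–60 nt.

* *Disease signal*: when `disease_state = 1`, a fixed motif (default
  `GGCATG`, 6 nt) is implanted into a fraction `phi` (default 0.2) of the
  sequences at a uniform valid offset. Healthy repertoires carry the motif
  only at the background rate, which for uniform sequences has the closed
  form `E[count per sequence] = (L - k + 1) / 4^k` — the oracle the tests
  use.
* *Age–diversity*: sequences are drawn from a clone pool of size
  `max(pool_min, round(pool_max * exp(-age / tau)))` (defaults 20, `m`,
  40 years): older patients draw from fewer clones, so distinct-sequence
  counts decrease with age. The exponential form is this package's choice
  — the phenomenon it emulates is directional only — picked because it is
  monotone, has one interpretable time constant, and is trivially
  replaceable. When the pool is at least `m`, draws are made *without*
  replacement, so young repertoires are exactly i.i.d. uniform and the
  closed-form motif oracle applies.
* *Protocol bias*: each protocol carries a 4×4 row-stochastic nucleotide
  substitution matrix applied position-independently **to the clone pool**
  (copies of a clone must stay identical, or the bias would erase the
  age–diversity signal). The default `amplicon` protocol shifts A→G and
  T→C with probability 0.1, a detectable GC shift; `baseline` is the
  identity; `bias_strength = 0` disables the contrast.

These defaults make the repertoires a usable benchmark for
signal-detection methods, not biologically realistic data: there is no
V(D)J recombination, no germline gene usage, no clonal expansion dynamics,
and background sequences are uniform rather than position-biased. Passing
tests demonstrate that the *declared* signals (motif enrichment, age
effect, protocol shift) are present and detectable at the declared
strengths — they say nothing about performance on real AIRR data.

## Numerical and degenerate-input choices

* Statistical tests in the suite use fixed seeds and 3-standard-error
  bands around analytic values (binomial/rejection/k-mer oracles), or
  exact combinatorial checks where enumeration is feasible.
* `p = 0` and `p = 1` probabilities are honoured exactly (no clamping),
  so degenerate nodes are usable as constants.
* A selection function returning anything but a single `TRUE`/`FALSE`, or
  a stratify label that is not a non-missing scalar, is a kind/label
  error, not a silent coercion.
* Problem sizes in the tests — 10⁴ samples for the calibration checks,
  4096 graphs for the exhaustive acyclicity sweep, 50 patients per arm at
  `m = 500` for the repertoire contrasts, 20 replicates for the age sign
  test — were chosen so every statistical check has power well above its
  3-SE band while the whole suite runs in well under a minute.

## Known limitations

* One selection and one stratify node per graph; no composition semantics.
* No interventions/counterfactual surgery, no time-series (dynamic
  Bayesian network) support, no nested plates — all out of scope.
* Rejection sampling is exact but can be arbitrarily slow for rare
  acceptance events; the budget converts that into a diagnosable error
  rather than a hang.
* The YAML dialect is this package's own; it does not claim
  byte-compatibility with any other tool's format.
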