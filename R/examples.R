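# Stock per-sample samplers, usable directly as node functions from YAML.
# All draw from R's global RNG stream so a single master seed makes the
# whole run reproducible.

#' Stock node functions
#'
#' Small per-sample samplers covering the common cases so simple nodes can
#' be declared in YAML without writing code: one draw per call, from the
#' global RNG stream.
#'
#' @param min,max Bounds of the uniform draw.
#' @param low,high Inclusive integer bounds.
#' @param p Success probability.
#' @param mean,sd Normal parameters.
#' @param labels Category labels.
#' @param probs Optional category probabilities (must sum to 1).
#' @return A single draw.
#' @name stock-samplers
NULL

#' @rdname stock-samplers
#' @export
rand_uniform <- function(min = 0, max = 1) stats::runif(1L, min, max)

#' @rdname stock-samplers
#' @export
rand_int <- function(low, high) {
  if (high < low) sim_abort("simdag_domain_error", "rand_int: high < low")
  low + sample.int(high - low + 1L, 1L) - 1L
}

#' @rdname stock-samplers
#' @export
rand_bernoulli <- function(p = 0.5) {
  check_probability(p, "p")
  stats::rbinom(1L, 1L, p)
}

#' @rdname stock-samplers
#' @export
rand_normal <- function(mean = 0, sd = 1) stats::rnorm(1L, mean, sd)

#' @rdname stock-samplers
#' @export
rand_categorical <- function(labels, probs = NULL) {
  if (!is.null(probs)) {
    if (length(probs) != length(labels))
      sim_abort("simdag_config_error", "rand_categorical: probs and labels differ in length")
    if (abs(sum(probs) - 1) > 1e-8)
      sim_abort("simdag_config_error", "rand_categorical: probs must sum to 1")
  }
  sample(labels, 1L, prob = probs)
}

check_probability <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    sim_abort("simdag_domain_error", sprintf("%s must be a probability in [0, 1]", what))
  invisible(p)
}

#' Simulate one coin-toss sequence
#'
#' Draws `n_tosses` independent tosses, heads (`H`) with probability
#' `p_heads`, and returns them as one text string over the alphabet
#' `{H, T}`. Sequences are 10 to 20 tosses long.
#'
#' @param p_heads Probability of heads, in `[0, 1]`.
#' @param n_tosses Number of tosses, an integer in `[10, 20]`.
#' @return A string such as `"HTTHHTHTHH"`.
#' @examples
#' set.seed(1)
#' coin_toss_sequence(0.5, 12)
#' @export
coin_toss_sequence <- function(p_heads, n_tosses) {
  check_probability(p_heads, "p_heads")
  if (!is.numeric(n_tosses) || length(n_tosses) != 1L || is.na(n_tosses) ||
      n_tosses != round(n_tosses) || n_tosses < 10 || n_tosses > 20)
    sim_abort("simdag_domain_error", "n_tosses must be an integer in [10, 20]")
  paste(sample(c("H", "T"), n_tosses, replace = TRUE,
               prob = c(p_heads, 1 - p_heads)), collapse = "")
}

#' The coin-toss example graph
#'
#' Three nodes: a per-sample heads probability drawn uniformly on
#' `[0, 1]`, a toss count drawn uniformly from `{10, ..., 20}`, and the
#' toss sequence itself with both as parents.
#'
#' @return A `dag_graph`.
#' @export
coin_toss_graph <- function() {
  build_graph(list(
    node("p_heads", func = "simdag::rand_uniform", args = list(min = 0, max = 1)),
    node("n_tosses", func = "simdag::rand_int", args = list(low = 10L, high = 20L)),
    node("sequence", func = "simdag::coin_toss_sequence",
         args = list(p_heads = node_ref("p_heads"), n_tosses = node_ref("n_tosses")))
  ), name = "coin_toss")
}
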