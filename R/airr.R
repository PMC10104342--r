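#' Generator settings for simulated immune repertoires
#'
#' Defaults chosen as a stylised but realistic benchmark: 500 sequences
#' per repertoire, lengths uniform on 30-60 nt (CDR3-scale), a 6-mer
#' disease motif implanted into 20% of a diseased patient's sequences,
#' clone-pool size decaying exponentially with age (time constant 40
#' years, floor of 20 clones), and a mild GC-shift substitution bias for
#' the non-baseline protocol.
#'
#' @param m Sequences per repertoire.
#' @param len_range Integer length range (min, max) in nucleotides.
#' @param motif Disease motif (string over ACGT) implanted when
#'   `disease_state = 1`.
#' @param phi Fraction of sequences receiving the motif in diseased
#'   repertoires.
#' @param pool_max Clone-pool size at age 0 (defaults to `m`).
#' @param pool_min Clone-pool floor at high age.
#' @param tau Age time constant (years) of the pool-size decay.
#' @param protocols Named list mapping protocol labels to 4x4
#'   row-stochastic nucleotide substitution matrices (rows/cols in order
#'   A, C, G, T); a protocol absent from the list gets the identity (no
#'   bias).
#' @param bias_strength Off-diagonal mass of the default `amplicon`
#'   protocol's substitution matrix; 0 disables the bias.
#' @return A list of settings of class `airr_params`.
#' @export
airr_params <- function(m = 500L, len_range = c(30L, 60L), motif = "GGCATG",
                        phi = 0.2, pool_max = m, pool_min = 20L, tau = 40,
                        protocols = NULL, bias_strength = 0.1) {
  if (m < 1L) sim_abort("simdag_config_error", "m must be >= 1")
  if (length(len_range) != 2L || len_range[1L] > len_range[2L] || len_range[1L] < 1L)
    sim_abort("simdag_config_error", "len_range must be an increasing positive pair")
  if (!grepl("^[ACGT]+$", motif))
    sim_abort("simdag_config_error", "motif must be a non-empty string over A, C, G, T")
  if (nchar(motif) > len_range[1L])
    sim_abort("simdag_config_error", "motif is longer than the minimum sequence length")
  check_probability(phi, "phi")
  if (is.null(protocols)) {
    nt <- c("A", "C", "G", "T")
    id <- diag(4); dimnames(id) <- list(nt, nt)
    gc_shift <- id
    # A->G and T->C with probability bias_strength: shifts composition to GC
    gc_shift["A", "A"] <- 1 - bias_strength; gc_shift["A", "G"] <- bias_strength
    gc_shift["T", "T"] <- 1 - bias_strength; gc_shift["T", "C"] <- bias_strength
    protocols <- list(baseline = id, amplicon = gc_shift)
  }
  for (pm in protocols) {
    if (!is.matrix(pm) || any(dim(pm) != 4L) || any(pm < 0) ||
        any(abs(rowSums(pm) - 1) > 1e-8))
      sim_abort("simdag_config_error", "each protocol matrix must be 4x4 row-stochastic")
  }
  structure(list(m = as.integer(m), len_range = as.integer(len_range),
                 motif = motif, phi = phi, pool_max = as.integer(pool_max),
                 pool_min = as.integer(pool_min), tau = tau,
                 protocols = protocols),
            class = "airr_params")
}

random_dna <- function(n, len_range) {
  lens <- len_range[1L] + sample.int(len_range[2L] - len_range[1L] + 1L, n,
                                     replace = TRUE) - 1L
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
}

#' Simulate one adaptive immune receptor repertoire
#'
#' Generates the set of receptor DNA sequences for one simulated patient,
#' conditioned on disease state, age and experimental protocol:
#'
#' * background sequences are i.i.d. uniform over A/C/G/T with lengths
#'   uniform in `params$len_range`;
#' * diversity decreases with age: sequences are drawn from a clone pool of
#'   size `max(pool_min, round(pool_max * exp(-age / tau)))`, so older
#'   patients repeat clones more often (without replacement when the pool
#'   is at least `m`, with replacement otherwise);
#' * the protocol applies its position-independent nucleotide substitution
#'   matrix, emulating protocol-specific sequence bias;
#' * when `disease_state = 1`, the disease motif is implanted into a
#'   fraction `phi` of the sequences at a uniform random valid offset,
#'   creating the ground-truth disease signal.
#'
#' @param disease_state 0 (healthy) or 1 (diseased).
#' @param age Patient age in years (>= 0).
#' @param protocol Protocol label; must be named in `params$protocols`.
#' @param params An [airr_params()] object.
#' @return An object of class `repertoire`: list with `sequences`
#'   (character vector), the metadata, and `implanted` (indices of
#'   motif-implanted sequences).
#' @examples
#' set.seed(1)
#' rep <- airr_repertoire(1, age = 30, protocol = "baseline",
#'                        params = airr_params(m = 50))
#' length(rep$sequences)
#' @export
airr_repertoire <- function(disease_state, age, protocol = "baseline",
                            params = airr_params()) {
  if (!disease_state %in% c(0, 1))
    sim_abort("simdag_domain_error", "disease_state must be 0 or 1")
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age < 0)
    sim_abort("simdag_domain_error", "age must be a non-negative number of years")
  if (!protocol %in% names(params$protocols))
    sim_abort("simdag_domain_error", sprintf(
      "unknown protocol '%s' (configured: %s)", protocol,
      paste(names(params$protocols), collapse = ", ")))

  m <- params$m
  pool_size <- max(params$pool_min,
                   as.integer(round(params$pool_max * exp(-age / params$tau))))
  pool <- random_dna(pool_size, params$len_range)
  # bias the pool, not the drawn copies: replicates of a clone must stay
  # identical or the age-diversity signal would be washed out
  pool <- apply_protocol_bias(pool, params$protocols[[protocol]])
  idx <- if (pool_size >= m) sample.int(pool_size, m, replace = FALSE)
         else sample.int(pool_size, m, replace = TRUE)
  seqs <- pool[idx]

  implanted <- integer(0)
  if (disease_state == 1) {
    k <- nchar(params$motif)
    n_implant <- round(params$phi * m)
    if (n_implant > 0L) {
      implanted <- sample.int(m, n_implant)
      for (i in implanted) {
        L <- nchar(seqs[i])
        off <- rand_int(1L, L - k + 1L)
        substr(seqs[i], off, off + k - 1L) <- params$motif
      }
    }
  }

  structure(list(sequences = seqs, disease_state = disease_state, age = age,
                 protocol = protocol, implanted = sort(implanted)),
            class = "repertoire")
}

apply_protocol_bias <- function(seqs, sub_matrix) {
  if (all(abs(sub_matrix - diag(4)) < 1e-12)) return(seqs)
  nt <- c("A", "C", "G", "T")
  cum <- t(apply(sub_matrix, 1L, cumsum))
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    ri <- match(chars, nt)
    u <- stats::runif(length(ri))
    hit <- u <= cum[ri, , drop = FALSE]  # first TRUE column = sampled base
    paste(nt[max.col(hit, ties.method = "first")], collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf(
    "<repertoire: %d sequences (%d distinct), disease_state=%d, age=%g, protocol=%s>\n",
    length(x$sequences), length(unique(x$sequences)), x$disease_state, x$age,
    x$protocol))
  invisible(x)
}

#' Simulate one patient's metadata
#'
#' Independent draws of disease state, age and protocol, suitable as a
#' single parent node of a repertoire node (or use three separate stock
#' sampler nodes).
#'
#' @param prevalence Disease prevalence in `[0, 1]`.
#' @param age_range Age range (years), sampled uniformly.
#' @param protocol_freqs Named vector of protocol frequencies (must sum
#'   to 1).
#' @return A list with `disease_state`, `age`, `protocol`.
#' @export
patient_metadata <- function(prevalence = 0.3, age_range = c(0, 100),
                             protocol_freqs = c(baseline = 0.5, amplicon = 0.5)) {
  check_probability(prevalence, "prevalence")
  if (is.null(names(protocol_freqs)) || any(!nzchar(names(protocol_freqs))))
    sim_abort("simdag_config_error", "protocol_freqs must be a named vector")
  if (abs(sum(protocol_freqs) - 1) > 1e-8)
    sim_abort("simdag_config_error", "protocol_freqs must sum to 1")
  list(
    disease_state = stats::rbinom(1L, 1L, prevalence),
    age = stats::runif(1L, age_range[1L], age_range[2L]),
    protocol = sample(names(protocol_freqs), 1L, prob = protocol_freqs)
  )
}

#' Count sequences containing the motif
#'
#' @param x A `repertoire` or character vector of sequences.
#' @param motif Motif string.
#' @return Number of sequences with at least one motif occurrence.
#' @export
motif_bearing_count <- function(x, motif) {
  seqs <- if (inherits(x, "repertoire")) x$sequences else x
  sum(grepl(motif, seqs, fixed = TRUE))
}

#' @rdname airr_repertoire
#' @param m,len_min,len_max,motif,phi Scalar generator settings (see
#'   [airr_params()]); this wrapper builds the settings internally so the
#'   node is fully expressible in YAML.
#' @export
airr_repertoire_node <- function(disease_state, age, protocol = "baseline",
                                 m = 500L, len_min = 30L, len_max = 60L,
                                 motif = "GGCATG", phi = 0.2) {
  airr_repertoire(disease_state, age, protocol,
                  params = airr_params(m = m, len_range = c(len_min, len_max),
                                       motif = motif, phi = phi))
}

#' The immune-repertoire example graph
#'
#' Patient-level metadata nodes (disease state, age, protocol) are the
#' parents of the repertoire node, one sample per patient.
#'
#' @param prevalence Disease prevalence.
#' @param m Sequences per repertoire.
#' @param phi Implanted fraction in diseased repertoires.
#' @return A `dag_graph`.
#' @export
airr_graph <- function(prevalence = 0.3, m = 500L, phi = 0.2) {
  build_graph(list(
    node("disease_state", func = "simdag::rand_bernoulli",
         args = list(p = prevalence)),
    node("age", func = "simdag::rand_uniform", args = list(min = 0, max = 100)),
    node("protocol", func = "simdag::rand_categorical",
         args = list(labels = c("baseline", "amplicon"))),
    node("repertoire", func = "simdag::airr_repertoire_node",
         args = list(disease_state = node_ref("disease_state"),
                     age = node_ref("age"), protocol = node_ref("protocol"),
                     m = m, phi = phi))
  ), name = "airr")
}
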