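test_that("degenerate heads probabilities give constant sequences", {
  set.seed(1)
  expect_identical(coin_toss_sequence(1, 10), strrep("H", 10))
  expect_identical(coin_toss_sequence(0, 12), strrep("T", 12))
  expect_error(coin_toss_sequence(1.2, 10), class = "simdag_domain_error")
  expect_error(coin_toss_sequence(0.5, 9), class = "simdag_domain_error")
  expect_error(coin_toss_sequence(0.5, 21), class = "simdag_domain_error")
})

test_that("fair tosses pool to an H-fraction near one half", {
  set.seed(10)
  n <- 5000L
  seqs <- vapply(seq_len(n), function(i) coin_toss_sequence(0.5, 10L), "")
  pooled <- paste(seqs, collapse = "")
  heads <- sum(strsplit(pooled, "")[[1]] == "H")
  total <- nchar(pooled)
  expect_lt(abs(heads / total - 0.5), 3 * sqrt(0.25 / total))
})

test_that("coin-toss model end to end: lengths, alphabet, p-H coupling", {
  tab <- simulate_graph(coin_toss_graph(), n_samples = 2000, seed = 77)
  seqs <- unlist(tab[["sequence"]])
  lens <- nchar(seqs)
  expect_true(all(lens >= 10 & lens <= 20))
  expect_true(all(grepl("^[HT]+$", seqs)))
  h_frac <- vapply(seqs, function(s)
    mean(strsplit(s, "")[[1]] == "H"), 0, USE.NAMES = FALSE)
  p <- unlist(tab[["p_heads"]])
  expect_gt(stats::cor(p, h_frac, method = "spearman"), 0.5)
})

test_that("shape image with zero probabilities is exactly black", {
  set.seed(2)
  img <- shape_image(0, 0, 0, 0)
  expect_true(all(img$pixels == 0))
  expect_length(img$fired, 0L)
  expect_error(shape_image(-0.1, 0, 0, 0), class = "simdag_domain_error")
})

test_that("a forced circle matches a brute-force disc rasterization", {
  for (seed in 1:5) {
    set.seed(seed)
    img <- shape_image(0, 1, 0, 0)
    geo <- img$fired$circle
    expect_false(is.null(geo))
    size <- nrow(img$pixels)
    oracle <- matrix(0, size, size)
    for (y in seq_len(size)) for (x in seq_len(size)) {
      if ((y - geo$cy)^2 + (x - geo$cx)^2 <= geo$radius^2) oracle[y, x] <- 1
    }
    expect_identical(img$pixels, oracle)
  }
})

test_that("each shape fires at its nominal frequency and intensities stay in [0,1]", {
  set.seed(11)
  n <- 2000L
  fired <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, c("vertical_bar", "circle",
                                          "rectangle", "horizontal_bar")))
  for (i in seq_len(n)) {
    img <- shape_image(0.5, 0.5, 0.5, 0.5, size = 32L)
    fired[i, names(img$fired)] <- TRUE
    expect_true(all(img$pixels %in% c(0, 1)))
  }
  se <- sqrt(0.25 / n)
  for (sh in colnames(fired))
    expect_lt(abs(mean(fired[, sh]) - 0.5), 3 * se)
})

test_that("healthy repertoires carry the motif at the analytic background rate", {
  # expected motif count per sequence of length L is (L - k + 1) / 4^k;
  # at age 0 the pool covers the repertoire, so sequences are i.i.d. uniform
  set.seed(5)
  params <- airr_params(m = 2000L)
  rep <- airr_repertoire(0, age = 0, protocol = "baseline",
                         params = airr_params(m = 2000L, pool_max = 2000L))
  k <- nchar(params$motif)
  counts <- vapply(rep$sequences, function(s) {
    L <- nchar(s)
    sum(vapply(seq_len(L - k + 1L), function(i)
      substr(s, i, i + k - 1L) == params$motif, TRUE))
  }, 0, USE.NAMES = FALSE)
  lens <- nchar(rep$sequences)
  expected <- sum(lens - k + 1) / 4^k
  expect_lt(abs(sum(counts) - expected), 3 * sqrt(expected) + 1)
})

test_that("diseased repertoires carry the motif in phi of sequences plus background", {
  set.seed(6)
  params <- airr_params(m = 1000L, phi = 0.2)
  rep <- airr_repertoire(1, age = 0, protocol = "baseline", params = params)
  expect_length(rep$implanted, 200L)
  frac <- motif_bearing_count(rep, params$motif) / params$m
  background <- mean(45 - 6 + 1) / 4^6 # approx per-sequence hit probability
  target <- 0.2 + (1 - 0.2) * background
  expect_lt(abs(frac - target), 3 * sqrt(target * (1 - target) / params$m))
})

test_that("repertoire diversity decreases with age", {
  set.seed(7)
  params <- airr_params(m = 500L)
  distinct_at <- function(age) {
    r <- airr_repertoire(0, age = age, protocol = "baseline", params = params)
    length(unique(r$sequences))
  }
  # strict decrease between the age extremes, per replicate
  wins <- vapply(1:20, function(i) distinct_at(0) > distinct_at(100), TRUE)
  expect_identical(sum(wins), 20L) # sign test: P(20/20 | p=1/2) = 2^-20
  # non-increasing expected distinct count over an age grid
  ages <- c(0, 25, 50, 75, 100)
  means <- vapply(ages, function(a)
    mean(vapply(1:20, function(i) distinct_at(a), 0)), 0)
  expect_true(all(diff(means) <= 0))
})

test_that("protocol bias shifts nucleotide composition detectably", {
  set.seed(8)
  params <- airr_params(m = 500L)
  comp <- function(protocol) {
    r <- airr_repertoire(0, age = 0, protocol = protocol, params = params)
    table(factor(strsplit(paste(r$sequences, collapse = ""), "")[[1]],
                 levels = c("A", "C", "G", "T")))
  }
  tab <- rbind(baseline = comp("baseline"), amplicon = comp("amplicon"))
  expect_lt(stats::chisq.test(tab)$p.value, 0.01)
  # and no detectable difference once the bias is disabled
  params0 <- airr_params(m = 500L, bias_strength = 0)
  comp0 <- function(protocol) {
    r <- airr_repertoire(0, age = 0, protocol = protocol, params = params0)
    table(factor(strsplit(paste(r$sequences, collapse = ""), "")[[1]],
                 levels = c("A", "C", "G", "T")))
  }
  tab0 <- rbind(comp0("baseline"), comp0("amplicon"))
  expect_gt(stats::chisq.test(tab0)$p.value, 0.01)
})

test_that("motif enrichment separates diseased from healthy cohorts", {
  set.seed(9)
  params <- airr_params(m = 500L, phi = 0.2)
  frac <- function(state) vapply(1:50, function(i) {
    r <- airr_repertoire(state, age = stats::runif(1, 0, 100),
                         protocol = "baseline", params = params)
    motif_bearing_count(r, params$motif) / params$m
  }, 0)
  healthy <- frac(0); diseased <- frac(1)
  expect_lt(stats::wilcox.test(diseased, healthy,
                               alternative = "greater")$p.value, 0.01)
})

test_that("patient metadata draws honour their distributions", {
  set.seed(12)
  expect_identical(patient_metadata(prevalence = 1)$disease_state, 1L)
  expect_identical(patient_metadata(prevalence = 0)$disease_state, 0L)
  draws <- replicate(2000, patient_metadata(prevalence = 0.3), simplify = FALSE)
  prev <- mean(vapply(draws, `[[`, 0L, "disease_state"))
  expect_lt(abs(prev - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  protos <- vapply(draws, `[[`, "", "protocol")
  expect_setequal(unique(protos), c("baseline", "amplicon"))
  expect_error(patient_metadata(protocol_freqs = c(a = 0.5, b = 0.6)),
               class = "simdag_config_error")
})

test_that("generator settings are validated", {
  expect_error(airr_params(motif = "XYZ"), class = "simdag_config_error")
  expect_error(airr_params(len_range = c(5L, 60L), motif = "GGCATG"),
               class = "simdag_config_error")
  expect_error(airr_repertoire(2, 10), class = "simdag_domain_error")
  expect_error(airr_repertoire(0, -1), class = "simdag_domain_error")
  expect_error(airr_repertoire(0, 10, protocol = "nope"),
               class = "simdag_domain_error")
})
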