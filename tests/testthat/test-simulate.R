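small_params <- function(...) {
  defaults <- list(G = 60, D = 6, conditions_per_dataset = 4,
                   replicates_per_condition = 2, module_sizes = 8L,
                   rng_seed = 515)
  do.call(corpus_params, utils::modifyList(defaults, list(...)))
}

test_that("simulate_corpus is a pure function of its parameters", {
  p <- small_params()
  s1 <- simulate_corpus(p)
  s2 <- simulate_corpus(p)
  expect_identical(s1, s2)
  s3 <- simulate_corpus(small_params(rng_seed = 99))
  expect_false(identical(s1$datasets[[1]]$values, s3$datasets[[1]]$values))
  # shape and labelling
  expect_length(s1$datasets, 6)
  ds <- s1$datasets[[1]]
  expect_equal(dim(ds), c(60L, 8L))
  expect_equal(length(unique(ds$condition_of)), 4L)
  expect_length(s1$truth$module_members[[1]], 8)
  expect_length(s1$truth$background, 52)
  # modules and background partition the universe
  expect_setequal(c(s1$truth$module_members[[1]], s1$truth$background),
                  rownames(ds$values))
})

test_that("simulated corpora pass QC by construction at the defaults", {
  s <- simulate_corpus(small_params(missing_rate = 0.02))
  pre <- preprocess_corpus(s$datasets)
  expect_true(all(vapply(pre$qc, `[[`, TRUE, "kept")))
  expect_length(pre$matrices, 6)
})

test_that("the linear-scale switch exercises the log transform path", {
  p <- small_params(linear_scale = TRUE, missing_rate = 0)
  s <- simulate_corpus(p)
  expect_gt(max(s$datasets[[1]]$values, na.rm = TRUE), 25)
  back <- maybe_log_transform(s$datasets[[1]])
  p2 <- small_params(linear_scale = FALSE, missing_rate = 0)
  direct <- simulate_corpus(p2)$datasets[[1]]
  expect_equal(back$values, direct$values, tolerance = 1e-12)
})

test_that("a noiseless always-firing module attains pairwise ratio 1", {
  p <- corpus_params(G = 30, D = 4, conditions_per_dataset = 3,
                     replicates_per_condition = 1, module_sizes = 5L,
                     co_de_prob = 1, background_de_rate = 0.1,
                     noise_sd = 0, missing_rate = 0, rng_seed = 4)
  s <- simulate_corpus(p)
  pre <- preprocess_corpus(s$datasets)
  map <- build_map(pre$matrices, gene_list(rownames(s$datasets[[1]]$values)))
  mod <- s$truth$module_members[[1]]
  for (a in mod[1:2]) {
    for (b in setdiff(mod, a)) {
      expect_equal(coexpression_ratio(map, a, b), 1.0)
    }
  }
})

test_that("null corpus: per-comparison differential rate matches theory", {
  # noiseless generator, per-condition jump probability q: a gene is
  # differential in a comparison iff the two conditions' shifts differ.
  # Comparisons within a dataset share conditions, so per-gene Q moments
  # come from enumerating the 3^C condition-state space (the oracle),
  # not from a naive independent-comparison binomial.
  q <- 0.1
  C <- 4
  p <- corpus_params(G = 200, D = 20, conditions_per_dataset = C,
                     replicates_per_condition = 1, module_sizes = integer(),
                     background_de_rate = q, noise_sd = 0, missing_rate = 0,
                     rng_seed = 8)
  datasets <- null_corpus(p)
  pre <- preprocess_corpus(datasets)
  map <- build_map(pre$matrices, gene_list(rownames(datasets[[1]]$values)))
  states <- as.matrix(expand.grid(rep(list(0:2), C)))  # 0 none, 1 up, 2 down
  prob_state <- apply(states, 1, function(s) prod(ifelse(s == 0, 1 - q, q / 2)))
  pair_idx <- utils::combn(C, 2)
  de_count <- apply(states, 1, function(s) {
    sum(s[pair_idx[1, ]] != s[pair_idx[2, ]])
  })
  Eq <- sum(prob_state * de_count)            # per-dataset expected DE count
  Vq <- sum(prob_state * de_count^2) - Eq^2
  n_cmp <- ncol(pair_idx)
  # the closed form per comparison agrees with the enumeration
  expect_equal(Eq / n_cmp, 2 * q * (1 - q) + q^2 / 2, tolerance = 1e-12)
  D <- length(pre$matrices)
  expect_equal(map$x, D * n_cmp)
  # per-gene Q within 4.5 sd of the enumerated moments (genes independent)
  expect_true(all(abs(map$Q - D * Eq) <= 4.5 * sqrt(D * Vq)))
  # the mean over 200 independent genes is far tighter
  expect_lt(abs(mean(map$Q) - D * Eq), 4 * sqrt(D * Vq / length(map$Q)))
  # independence: no pair reaches ratio 1 with appreciable Q
  N <- map$N; diag(N) <- 0L
  hi <- which(map$Q >= 10)
  r_cols <- sweep(N[, hi, drop = FALSE], 2, map$Q[hi], "/")
  expect_lt(max(r_cols), 1)
})

test_that("dose response: co_de_prob raises the within-module ratio", {
  # grid where the per-comparison module DE probability 2q(1-q) + q^2/2
  # is increasing in q (it peaks at q = 2/3, so 0.9 would NOT qualify);
  # a real noise floor makes the ratio respond to the dose
  mean_mod_ratio <- function(prob) {
    p <- corpus_params(G = 40, D = 25, conditions_per_dataset = 4,
                       replicates_per_condition = 1, module_sizes = 6L,
                       co_de_prob = prob, background_de_rate = 0.1,
                       noise_sd = 0.5, missing_rate = 0, rng_seed = 21)
    s <- simulate_corpus(p)
    map <- build_map(preprocess_corpus(s$datasets)$matrices,
                     gene_list(rownames(s$datasets[[1]]$values)))
    mod <- s$truth$module_members[[1]]
    pairs <- utils::combn(mod, 2)
    mean(vapply(seq_len(ncol(pairs)), function(i) {
      coexpression_ratio(map, pairs[1, i], pairs[2, i])
    }, 1), na.rm = TRUE)
  }
  grid <- vapply(c(0.1, 0.4, 0.7), mean_mod_ratio, 1)
  expect_true(all(diff(grid) >= 0))
})

test_that("degenerate generators behave as stated", {
  # nothing differential: Q is identically zero
  p <- corpus_params(G = 20, D = 2, conditions_per_dataset = 3,
                     module_sizes = integer(), background_de_rate = 0,
                     noise_sd = 0, missing_rate = 0, rng_seed = 3)
  datasets <- null_corpus(p)
  map <- build_map(preprocess_corpus(datasets)$matrices,
                   gene_list(rownames(datasets[[1]]$values)))
  expect_true(all(map$Q == 0L))
  expect_true(all(map$N == 0L))
  # missing_rate = 1: every dataset rejected upstream, not an error
  p2 <- corpus_params(G = 10, D = 2, conditions_per_dataset = 2,
                      module_sizes = integer(), missing_rate = 1,
                      rng_seed = 3)
  pre <- preprocess_corpus(null_corpus(p2))
  expect_length(pre$matrices, 0)
  expect_true(all(!vapply(pre$qc, `[[`, TRUE, "kept")))
  # parameter validation
  expect_error(corpus_params(G = 10, module_sizes = 20L), "exceeds")
  expect_error(corpus_params(co_de_prob = 1.2), "co_de_prob")
  expect_error(corpus_params(effect_size_log2 = 0.5), "effect_size")
})

test_that("write_corpus emits a loadable manifest and truth files", {
  dir <- tempfile("corpus")
  p <- small_params(n_tf = 5L)
  s <- simulate_corpus(p)
  manifest <- write_corpus(s, dir, p)
  expect_true(file.exists(manifest))
  loaded <- load_corpus(read_corpus_manifest(manifest))
  expect_length(loaded$datasets, length(s$datasets))
  expect_equal(loaded$datasets[[1]]$values, s$datasets[[1]]$values)
  expect_identical(loaded$datasets[[1]]$condition_of,
                   s$datasets[[1]]$condition_of)
  expect_true(file.exists(file.path(dir, "universe.txt")))
  expect_length(readLines(file.path(dir, "tfs.txt")), 5)
  cfg <- read_flat_config(file.path(dir, "params.cfg"))
  expect_equal(cfg$G, 60)
})
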