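test_that("call_differential honours the inclusive 2-fold boundary and missingness", {
  v <- matrix(c(4.0, 5.0,    # exactly 1 log2 unit -> +1
                4.0, 4.9,    # below cutoff -> 0
                5.0, 3.0,    # -2 log2 units -> -1
                NA,  7.0),   # missing -> absent
              nrow = 4, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:4), c("A", "B")))
  cm <- make_cm(v)
  calls <- call_differential(cm, "A", "B")
  expect_identical(calls, c(g1 = 1L, g2 = 0L, g3 = -1L))
  # swapping the conditions negates every non-zero call
  expect_identical(call_differential(cm, "B", "A"), -calls)
  expect_error(call_differential(cm, "A", "A"), "differ")
  expect_error(call_differential(cm, "A", "Z"), "not in dataset")
})

test_that("build_map reproduces the hand-enumerated toy corpus", {
  map <- build_map(list(toy_cm()), gene_list(c("g1", "g2")))
  expect_equal(map$x, 3L)
  expect_equal(unname(map$Q), c(2L, 2L))
  expect_equal(map$N["g1", "g2"], 2L)
  # diagonal convention: N(g, g) = Q(g)
  expect_equal(unname(diag(map$N)), unname(map$Q))
  # both conditional ratios are 1
  expect_equal(coexpression_ratio(map, "g1", "g2"), 1.0)
  expect_equal(coexpression_ratio(map, "g2", "g1"), 1.0)
})

test_that("build_map matches the naive triple-loop oracle on random corpora", {
  set.seed(421)
  for (rep in 1:4) {
    G <- sample(5:20, 1)
    D <- sample(1:5, 1)
    cms <- random_toy_corpus(G, D, C = sample(2:4, 1))
    genes <- rownames(cms[[1]]$values)
    map <- build_map(cms, gene_list(genes))
    oracle <- naive_vote_recount(cms, genes)
    expect_identical(unname(map$N), unname(oracle$N))
    expect_identical(unname(map$Q), unname(oracle$Q))
    expect_identical(map$x, oracle$x)
  }
})

test_that("vote-map invariants hold on fuzzed corpora", {
  set.seed(99)
  cms <- random_toy_corpus(12, 4, C = 3)
  genes <- rownames(cms[[1]]$values)
  map <- build_map(cms, gene_list(genes))
  # symmetry
  expect_identical(map$N, t(map$N))
  # bounds: 0 <= N(a,b) <= min(Q(a), Q(b)) <= x
  Qmin <- outer(map$Q, map$Q, pmin)
  expect_true(all(map$N >= 0L))
  expect_true(all(map$N <= Qmin))
  expect_true(all(map$Q <= map$x))
  # direction invariance: relabelling conditions so every comparison flips
  flipped <- lapply(cms, function(cm) {
    v <- cm$values[, rev(colnames(cm$values))]
    make_cm(v, cm$dataset_id)
  })
  map2 <- build_map(flipped, gene_list(genes))
  expect_identical(map2$N, map$N)
  expect_identical(map2$Q, map$Q)
  expect_identical(map2$x, map$x)
  # monotonicity: adding a dataset weakly increases N, Q, x
  map3 <- build_map(c(cms, random_toy_corpus(12, 1)), gene_list(genes))
  expect_true(all(map3$N >= map$N))
  expect_true(all(map3$Q >= map$Q))
  expect_gte(map3$x, map$x)
  # genes outside the universe are ignored
  map4 <- build_map(cms, gene_list(genes[1:5]))
  expect_identical(map4$N, map$N[1:5, 1:5])
})

test_that("constant genes collect no votes and empty corpora error", {
  v <- matrix(c(5, 5, 5,
                1, 3, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "g2"), c("A", "B", "C")))
  map <- build_map(list(make_cm(v)), gene_list(c("flat", "g2")))
  expect_equal(map$Q[["flat"]], 0L)
  expect_true(all(map$N["flat", ] == 0L))
  expect_true(is.na(coexpression_ratio(map, "g2", "flat")))
  expect_error(build_map(list(), gene_list(c("a", "b"))), "empty")
  expect_error(coexpression_ratio(map, "nope", "g2"), "not in the map")
})

test_that("friends_of ranks by ratio with the documented tie-break", {
  # 4 genes; craft N and Q directly through a corpus is awkward, so build
  # from a corpus of duplicated/partial co-movers
  g <- c("a", "b", "c", "d")
  mk <- function(...) {
    v <- matrix(c(...), nrow = 4, byrow = TRUE,
                dimnames = list(g, c("c1", "c2")))
    make_cm(v, paste0("d", sample.int(1e6, 1)))
  }
  set.seed(5)
  cms <- list(
    mk(1, 3,  1, 3,  5, 5,  5, 5),  # a,b up together
    mk(1, 3,  1, 3,  3, 1,  5, 5),  # a,b up; c down
    mk(3, 1,  5, 5,  1, 3,  5, 5)   # a down alone; c up
  )
  map <- build_map(cms, gene_list(g))
  # Q: a=3, b=2, c=2, d=0; N(a,b)=2, N(a,c)=0, N(b,c)=0
  expect_equal(unname(map$Q), c(3L, 2L, 2L, 0L))
  fr <- friends_of(map, "a", fraction = 0.5)  # floor(0.5 * 3) = 1 friend
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$friend, "b")
  expect_equal(fr$ratio, 2 / 3)
  # ratio conditions on the *partner*: r(a|b) = N/Q(b) = 1 while r(b|a) = 2/3
  expect_equal(coexpression_ratio(map, "a", "b"), 1.0)
  # zero-Q gene: empty list
  expect_equal(nrow(friends_of(map, "d", 0.5)), 0L)
  # ties on ratio 0 between b's non-friends: broken by symbol
  fr_b <- friends_of(map, "b", fraction = 0.9)  # floor(0.9*3) = 2
  expect_equal(fr_b$friend[1], "a")
  expect_equal(fr_b$friend[2], "c")  # c before d lexicographically (tie at 0)
  expect_error(friends_of(map, "a", 1.2), "fraction")
})

test_that("friend tables conserve occurrences and are deterministic", {
  set.seed(31)
  cms <- random_toy_corpus(15, 5, C = 4, missing_rate = 0.05)
  genes <- rownames(cms[[1]]$values)
  map <- build_map(cms, gene_list(genes))
  ft <- build_friend_table(map, fraction = 0.3)
  m <- floor(0.3 * (length(genes) - 1))
  lens <- lengths(ft$idx)
  # identical list length for every gene with Q > 0, empty otherwise
  expect_true(all(lens[map$Q > 0] == m))
  expect_true(all(lens[map$Q == 0] == 0L))
  # no self-friendship
  for (i in seq_along(genes)) expect_false(i %in% ft$idx[[i]])
  # conservation: sum of occurrences = sum of list lengths
  expect_equal(sum(ft$occurrences), sum(lens))
  # tally agrees with a direct recount
  recount <- vapply(seq_along(genes), function(gi) {
    sum(vapply(ft$idx, function(ix) gi %in% ix, TRUE))
  }, 1L)
  expect_equal(unname(ft$occurrences), recount)
  # byte-for-byte determinism across runs
  expect_identical(ft, build_friend_table(map, fraction = 0.3))
  # global friend probability = occurrences / G
  expect_equal(global_friend_probability(ft, genes[[3]]),
               unname(ft$occurrences[[3]]) / length(genes))
})

test_that("duplicated expression rows are mutual rank-1 friends", {
  set.seed(12)
  base <- matrix(runif(30, 4, 10), 5, 6,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:6)))
  base["g2", ] <- base["g1", ]  # exact duplicate
  map <- build_map(list(make_cm(base)), gene_list(rownames(base)))
  ft <- build_friend_table(map, fraction = 0.3)  # 1 friend each
  expect_equal(friend_symbols(ft, "g1"), "g2")
  expect_equal(friend_symbols(ft, "g2"), "g1")
})

test_that("export_network emits each qualifying pair once, ordered", {
  map <- build_map(list(toy_cm()), gene_list(c("g1", "g2")))
  edges <- export_network(map, 0.8)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$gene_a, "g1")
  expect_equal(edges$gene_b, "g2")
  expect_equal(edges$ratio, 1.0)
  # cutoff above every ratio: empty edge list
  expect_equal(nrow(export_network(map, 1.0)), 1L)  # ratios are exactly 1
  v <- matrix(c(1, 3, 1, 5,
                2, 4, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("A", "B", "C", "D")))
  map2 <- build_map(list(make_cm(v)), gene_list(c("g1", "g2")))
  # Q(g1) = 5, Q(g2) = 3, N = 2: r(g1|g2) = 2/3, r(g2|g1) = 2/5 -- the
  # edge qualifies through the larger orientation only
  expect_equal(nrow(export_network(map2, 0.6)), 1L)
  expect_equal(export_network(map2, 0.6)$ratio, 2 / 3)
  expect_equal(nrow(export_network(map2, 0.7)), 0L)
  expect_error(export_network(map, 0), "cutoff")
  expect_error(export_network(map, 1.5), "cutoff")
})
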