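# Independent oracles and in-code fixtures shared across the suite.

# Naive triple-loop recount of the vote map: per comparison, per gene,
# per gene pair. Deliberately slow and independent of build_map's
# vectorised accumulation.
naive_vote_recount <- function(cms, genes, fold = 2) {
  G <- length(genes)
  N <- matrix(0L, G, G, dimnames = list(genes, genes))
  Q <- stats::setNames(integer(G), genes)
  x <- 0L
  thr <- log2(fold)
  for (cm in cms) {
    conds <- colnames(cm$values)
    if (length(conds) < 2L) next
    for (i in seq_len(length(conds) - 1L)) {
      for (j in seq((i + 1L), length(conds))) {
        x <- x + 1L
        dir <- rep(NA_integer_, G)
        for (gi in seq_len(G)) {
          g <- genes[[gi]]
          if (!g %in% rownames(cm$values)) next
          va <- cm$values[g, conds[[i]]]
          vb <- cm$values[g, conds[[j]]]
          if (is.na(va) || is.na(vb)) next
          d <- vb - va
          dir[[gi]] <- if (abs(d) >= thr) as.integer(sign(d)) else 0L
        }
        for (gi in seq_len(G)) {
          if (!is.na(dir[[gi]]) && dir[[gi]] != 0L) Q[[gi]] <- Q[[gi]] + 1L
        }
        for (a in seq_len(G)) {
          for (b in seq_len(G)) {
            if (!is.na(dir[[a]]) && !is.na(dir[[b]]) &&
                dir[[a]] != 0L && dir[[a]] == dir[[b]]) {
              N[a, b] <- N[a, b] + 1L
            }
          }
        }
      }
    }
  }
  list(N = N, Q = Q, x = x)
}

# Exhaustive right-tail enumeration: sum of exact binomial pmf terms.
binom_tail_enum <- function(k, n, p) {
  j <- seq(k, n)
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Build a ConditionMatrix directly (bypassing preprocessing) from a
# genes x conditions matrix of log2 means.
make_cm <- function(values, dataset_id = "toy") {
  structure(
    list(dataset_id = dataset_id, values = values,
         replicate_counts = stats::setNames(rep(1L, ncol(values)),
                                            colnames(values))),
    class = "ConditionMatrix"
  )
}

# The hand-enumerated toy corpus: one dataset, conditions A/B/C,
# gene g1 = (1, 3, 1), g2 = (2, 4, 2). The three comparisons (A,B),
# (A,C), (B,C) give x = 3, Q(g1) = Q(g2) = 2, N(g1,g2) = 2.
toy_cm <- function() {
  make_cm(matrix(c(1, 3, 1,
                   2, 4, 2),
                 nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("A", "B", "C"))))
}

# Random small condition matrices for fuzzing the oracle equivalence,
# with missing values sprinkled in.
random_toy_corpus <- function(G, D, C = 3, missing_rate = 0.1) {
  genes <- sprintf("t%02d", seq_len(G))
  lapply(seq_len(D), function(d) {
    v <- matrix(round(stats::runif(G * C, 4, 10), 2), G, C,
                dimnames = list(genes, sprintf("c%d", seq_len(C))))
    v[stats::runif(G * C) < missing_rate] <- NA_real_
    make_cm(v, sprintf("fuzz%02d", d))
  })
}

# Small in-memory ExpressionDataset.
make_ds <- function(values, condition_of, dataset_id = "ds1") {
  expression_dataset(dataset_id, values, condition_of)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
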