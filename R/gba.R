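# Guilt-by-association ranking: binomial right-tail scoring of every gene
# against a seed list, transcription-factor filtering, randomization-based
# calibration of the significance cutoff.

#' Right tail of the binomial distribution
#'
#' `Pr(K >= k)` for `K ~ Binomial(n, p)`, evaluated with a numerically
#' stable tail routine so that extreme values (for example 7.9e-34) are
#' representable rather than underflowing to zero. Exactly 1 at `k = 0`
#' and exactly `p^n` at `k = n`.
#'
#' @param k Non-negative integer count, `0 <= k <= n`.
#' @param n Positive integer number of trials.
#' @param p Success probability in \[0, 1\].
#' @return `Pr(K >= k)`.
#' @export
binomial_tail <- function(k, n, p) {
  if (!is_count(n, min = 1L)) stop2("n must be a positive integer")
  if (!all(vapply(k, is_count, TRUE))) stop2("k must be non-negative integer(s)")
  if (any(k > n)) stop2("k must not exceed n")
  if (!all(vapply(p, is_prob, TRUE))) stop2("p must lie in [0, 1]")
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Count seed genes whose friend lists contain a gene
#'
#' Friendship is directional: `k(g)` counts seed genes `s` with `g` in
#' `s`'s friend list, not the reverse. The seed is first restricted to the
#' universe and to genes with non-empty friend lists.
#'
#' @param ft A `FriendTable`.
#' @param seed A `GeneList` (or character vector) of seed symbols.
#' @param g Gene symbol to score.
#' @return Non-negative integer count.
#' @export
count_seed_friends <- function(ft, seed, g) {
  stopifnot(inherits(ft, "FriendTable"))
  eff <- effective_seed(ft, seed)
  i <- match(g, ft$genes)
  if (is.na(i)) stop2("gene '%s' not in the friend table", g)
  sum(vapply(eff$idx, function(ix) i %in% ft$idx[[ix]], TRUE))
}

# Restrict a seed list to universe genes with non-empty friend lists.
# Returns indices plus the dropped symbols, split by reason.
effective_seed <- function(ft, seed) {
  symbols <- if (inherits(seed, "GeneList")) seed$symbols else
    gene_list(seed, "seed")$symbols
  ix <- match(symbols, ft$genes)
  not_in_universe <- symbols[is.na(ix)]
  ix <- ix[!is.na(ix)]
  empty <- lengths(ft$idx[ix]) == 0L
  no_friend_list <- ft$genes[ix[empty]]
  ix <- ix[!empty]
  if (!length(ix)) stop2("seed list empty after restriction to the map")
  list(idx = ix, symbols = ft$genes[ix],
       dropped = c(not_in_universe, no_friend_list),
       dropped_not_in_universe = not_in_universe,
       dropped_no_friend_list = no_friend_list)
}

#' Rank all genes against a seed list
#'
#' For every universe gene `g` with a non-empty friend list: `k` is the
#' number of (effective) seed genes whose friend lists contain `g`, `p` is
#' `g`'s global friend probability, and the p-value is the binomial right
#' tail `Pr(K >= k)` with `n` the effective seed size. Seed genes are
#' scored like any other candidate. The table is sorted by ascending
#' p-value, then descending `k`, then symbol.
#'
#' @param ft A `FriendTable`.
#' @param seed A `GeneList` (or character vector) of seed symbols.
#' @param alpha Significance cutoff for the `significant` flag
#'   (default 1e-6).
#' @return A `GbaTable`: data frame with columns `rank`, `gene`, `k`, `n`,
#'   `p_background`, `pvalue`, `significant`; attributes `seed_name`,
#'   `effective_seed`, `dropped_not_in_universe`,
#'   `dropped_no_friend_list`, `excluded_q0` (genes without friend lists,
#'   not scored), `alpha`.
#' @export
rank_candidates <- function(ft, seed, alpha = 1e-6) {
  stopifnot(inherits(ft, "FriendTable"))
  if (!is_prob(alpha)) stop2("alpha must lie in [0, 1]")
  eff <- effective_seed(ft, seed)
  n <- length(eff$idx)
  G <- length(ft$genes)
  k <- tabulate(unlist(ft$idx[eff$idx], use.names = FALSE), nbins = G)
  scored <- which(lengths(ft$idx) > 0L)
  p <- ft$occurrences[scored] / G
  kv <- k[scored]
  pval <- stats::pbinom(kv - 1, size = n, prob = p, lower.tail = FALSE)
  tab <- data.frame(
    gene = ft$genes[scored],
    k = kv,
    n = n,
    p_background = unname(p),
    pvalue = unname(pval),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$pvalue, -tab$k, tab$gene, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab$significant <- tab$pvalue < alpha
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  seed_name <- if (inherits(seed, "GeneList")) seed$name else "seed"
  structure(tab,
            class = c("GbaTable", "data.frame"),
            seed_name = seed_name,
            effective_seed = eff$symbols,
            dropped_not_in_universe = eff$dropped_not_in_universe,
            dropped_no_friend_list = eff$dropped_no_friend_list,
            excluded_q0 = ft$genes[lengths(ft$idx) == 0L],
            alpha = alpha)
}

#' @export
print.GbaTable <- function(x, ...) {
  cat(sprintf(
    "<GbaTable> seed '%s' (n = %d effective), %d scored genes, %d significant at alpha = %g\n",
    attr(x, "seed_name"), length(attr(x, "effective_seed")),
    nrow(x), sum(x$significant), attr(x, "alpha")))
  NextMethod()
}

#' Restrict a ranked table to transcription factors
#'
#' Keeps records whose symbol is in the TF list, in their original order,
#' and renumbers ranks. P-values are not recomputed: they remain relative
#' to the full universe, matching a post-hoc filter of the genome-wide
#' ranking.
#'
#' @param table A `GbaTable` from [rank_candidates()].
#' @param tfs A `GeneList` (or character vector) of transcription factors.
#' @return A `GbaTable` restricted to TFs.
#' @export
filter_tfs <- function(table, tfs) {
  stopifnot(inherits(table, "GbaTable"))
  symbols <- if (inherits(tfs, "GeneList")) tfs$symbols else
    gene_list(tfs, "tfs")$symbols
  keep <- table$gene %in% symbols
  if (!any(keep)) warn2("no transcription factor appears in the ranked table")
  out <- table[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  for (a in c("seed_name", "effective_seed", "dropped_not_in_universe",
              "dropped_no_friend_list", "excluded_q0", "alpha")) {
    attr(out, a) <- attr(table, a)
  }
  class(out) <- c("GbaTable", "data.frame")
  out
}

#' Randomization-based calibration of the significance cutoff
#'
#' Draws `replicates` random seed lists (uniform, without replacement,
#' from genes with non-empty friend lists), ranks all genes against each,
#' and aggregates the resulting p-values. On a null corpus the minimum
#' p-value over replicates indicates how small a p-value chance alone can
#' produce, calibrating the reporting cutoff.
#'
#' @param ft A `FriendTable`.
#' @param seed_size Number of genes per random seed list (>= 2).
#' @param replicates Number of random seed lists (>= 1).
#' @param rng_seed Integer seed making the draw reproducible.
#' @return A `CalibrationReport`: list with `seed_size`, `replicates`,
#'   `rng_seed`, `min_pvalue`, `pvalue_quantiles`, `n_pvalues`.
#' @export
randomization_calibration <- function(ft, seed_size, replicates, rng_seed) {
  stopifnot(inherits(ft, "FriendTable"))
  if (!is_count(seed_size, 2L)) stop2("seed_size must be an integer >= 2")
  if (!is_count(replicates, 1L)) stop2("replicates must be an integer >= 1")
  eligible <- ft$genes[lengths(ft$idx) > 0L]
  if (seed_size > length(eligible)) {
    stop2("seed_size (%d) exceeds the %d eligible genes", seed_size,
          length(eligible))
  }
  pvals <- with_rng_seed(rng_seed, {
    unlist(lapply(seq_len(replicates), function(r) {
      s <- sample(eligible, seed_size)
      rank_candidates(ft, gene_list(s, sprintf("random_%d", r)))$pvalue
    }), use.names = FALSE)
  })
  qs <- stats::quantile(pvals, c(0.001, 0.01, 0.05, 0.5))
  structure(
    list(seed_size = as.integer(seed_size),
         replicates = as.integer(replicates),
         rng_seed = as.integer(rng_seed),
         min_pvalue = min(pvals),
         pvalue_quantiles = qs,
         n_pvalues = length(pvals)),
    class = "CalibrationReport"
  )
}

#' @export
print.CalibrationReport <- function(x, ...) {
  cat(sprintf(
    "<CalibrationReport> %d random seed lists of size %d (rng_seed %d): min p-value %.3g over %d scores\n",
    x$replicates, x$seed_size, x$rng_seed, x$min_pvalue, x$n_pvalues))
  invisible(x)
}

#' Write a calibration report as TSV
#'
#' @param report A `CalibrationReport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(report, path) {
  qn <- names(report$pvalue_quantiles)
  lines <- c("metric\tvalue",
             sprintf("seed_size\t%d", report$seed_size),
             sprintf("replicates\t%d", report$replicates),
             sprintf("rng_seed\t%d", report$rng_seed),
             sprintf("n_pvalues\t%d", report$n_pvalues),
             sprintf("min_pvalue\t%.6g", report$min_pvalue),
             sprintf("quantile_%s\t%.6g", qn, report$pvalue_quantiles))
  writeLines(lines, path)
  invisible(path)
}

#' Bonferroni coherence of the reporting cutoff
#'
#' Sanity check that the fixed reporting cutoff `alpha` is more stringent
#' than a Bonferroni-corrected 0.05 over a universe of `G + 1` tests
#' (matching the convention of correcting over 20,677 when the universe
#' has 20,676 symbols).
#'
#' @param G Universe size.
#' @param alpha Reporting cutoff (default 1e-6).
#' @return `TRUE` invisibly if coherent, otherwise an error.
#' @export
check_bonferroni <- function(G, alpha = 1e-6) {
  bon <- 0.05 / (G + 1)
  if (alpha >= bon) {
    stop2("alpha %g is not below the Bonferroni level 0.05/%d = %g",
          alpha, G + 1, bon)
  }
  invisible(TRUE)
}
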