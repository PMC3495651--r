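# The vote-counting co-expression map: per-comparison differential calls,
# corpus-level accumulation of N (joint same-direction calls), Q (per-gene
# differential counts) and x (total comparisons), co-expression ratios and
# threshold-network export.

#' Differential-expression calls for one condition pair
#'
#' For every gene with finite values in both conditions, the call is
#' `sign(v_b - v_a)` when the absolute log2 difference reaches
#' `log2(fold_threshold)` (inclusive boundary: exactly 2-fold counts), and
#' `0` otherwise. Genes missing either value are absent from the result.
#' Swapping the two conditions negates every non-zero call; the vote
#' counter only uses agreement of signs, so direction is irrelevant
#' downstream.
#'
#' @param cm A `ConditionMatrix` from [average_replicates()].
#' @param cond_a,cond_b Distinct condition labels present in `cm`.
#' @param fold_threshold Fold-change cutoff on the linear scale (default 2).
#' @return Named integer vector of calls in `{-1, 0, 1}`.
#' @export
call_differential <- function(cm, cond_a, cond_b, fold_threshold = 2) {
  stopifnot(inherits(cm, "ConditionMatrix"))
  if (identical(cond_a, cond_b)) stop2("cond_a and cond_b must differ")
  conds <- colnames(cm$values)
  if (!cond_a %in% conds || !cond_b %in% conds) {
    stop2("condition(s) not in dataset '%s'", cm$dataset_id)
  }
  if (fold_threshold < 1) stop2("fold_threshold must be >= 1")
  d <- cm$values[, cond_b] - cm$values[, cond_a]
  present <- !is.na(d)
  d <- d[present]
  calls <- integer(length(d))
  hit <- abs(d) >= log2(fold_threshold)
  calls[hit] <- as.integer(sign(d[hit]))
  stats::setNames(calls, rownames(cm$values)[present])
}

#' Build the corpus-level vote map
#'
#' Within each dataset every unordered pair of distinct conditions is
#' compared (a dataset with c conditions contributes `c*(c-1)/2`
#' comparisons). Per comparison, each gene called differentially expressed
#' increments its count Q, and each gene pair called in the same direction
#' increments its joint count N. Genes outside the universe are ignored.
#' The diagonal of N carries Q by convention.
#'
#' @param cms List of `ConditionMatrix` objects (a preprocessed corpus).
#' @param universe A `GeneList` (or character vector) fixing the gene
#'   universe; the map is G x G over these symbols.
#' @param fold_threshold Fold-change cutoff (default 2).
#' @return A `VoteMap`: list with `genes`, `N` (symmetric integer matrix),
#'   `Q` (integer vector), `x` (total comparisons), `presence` (per-gene
#'   count of comparisons in which the gene had finite values).
#' @export
build_map <- function(cms, universe, fold_threshold = 2) {
  if (!length(cms)) stop2("empty corpus")
  genes <- if (inherits(universe, "GeneList")) universe$symbols else
    gene_list(universe)$symbols
  G <- length(genes)
  N <- matrix(0L, G, G, dimnames = list(genes, genes))
  Q <- stats::setNames(integer(G), genes)
  presence <- stats::setNames(integer(G), genes)
  x <- 0L
  for (cm in cms) {
    conds <- colnames(cm$values)
    if (length(conds) < 2L) next
    idx_univ <- match(rownames(cm$values), genes)
    for (i in seq_len(length(conds) - 1L)) {
      for (j in seq((i + 1L), length(conds))) {
        x <- x + 1L
        calls <- call_differential(cm, conds[[i]], conds[[j]], fold_threshold)
        gi <- idx_univ[match(names(calls), rownames(cm$values))]
        keep <- !is.na(gi)
        gi <- gi[keep]
        calls <- calls[keep]
        presence[gi] <- presence[gi] + 1L
        up <- gi[calls == 1L]
        dn <- gi[calls == -1L]
        de <- c(up, dn)
        if (length(de)) Q[de] <- Q[de] + 1L
        if (length(up)) N[up, up] <- N[up, up] + 1L
        if (length(dn)) N[dn, dn] <- N[dn, dn] + 1L
      }
    }
  }
  structure(
    list(genes = genes, N = N, Q = Q, x = x, presence = presence,
         fold_threshold = fold_threshold),
    class = "VoteMap"
  )
}

#' @export
print.VoteMap <- function(x, ...) {
  cat(sprintf("<VoteMap> %d genes, %d comparisons, %d genes with Q > 0\n",
              length(x$genes), x$x, sum(x$Q > 0L)))
  invisible(x)
}

map_gene_index <- function(map, g) {
  i <- match(g, map$genes)
  if (is.na(i)) stop2("gene '%s' not in the map universe", g)
  i
}

#' Co-expression ratio of one gene given another
#'
#' `r(g | s) = N(g, s) / Q(s)`: the fraction of comparisons in which `s`
#' was differentially expressed where `g` co-moved in the same direction.
#' The ratio is conditional on `s`, so in general `r(g|s) != r(s|g)`.
#' Undefined (`NA`) when `Q(s) = 0`.
#'
#' @param map A `VoteMap`.
#' @param g,s Gene symbols in the universe; `s` is the conditioning gene.
#' @return Ratio in \[0, 1\], or `NA` if `s` was never differential.
#' @export
coexpression_ratio <- function(map, g, s) {
  stopifnot(inherits(map, "VoteMap"))
  ig <- map_gene_index(map, g)
  is <- map_gene_index(map, s)
  if (map$Q[[is]] == 0L) return(NA_real_)
  map$N[ig, is] / map$Q[[is]]
}

# Ranked friend indices for gene index `is`; shared by friends_of and
# build_friend_table. Orientation "partner" ranks by N(g,s)/Q(s) (the
# default; rank-equivalent to ranking by N), "self" by N(g,s)/Q(g).
friend_order <- function(map, is, orientation = "partner") {
  n <- map$N[, is]
  n[is] <- 0L
  r <- if (orientation == "partner") {
    if (map$Q[[is]] == 0L) return(NULL)
    n / map$Q[[is]]
  } else {
    q <- map$Q
    out <- ifelse(q > 0L, n / q, 0)
    out[is] <- 0
    out
  }
  cand <- setdiff(seq_along(map$genes), is)
  ord <- cand[order(-r[cand], -n[cand], map$genes[cand], method = "radix")]
  list(idx = ord, ratio = r[ord], n = n[ord])
}

#' Top-fraction friend list of a gene
#'
#' Candidates are every other universe gene, ranked by descending
#' co-expression ratio, ties broken by descending joint count N then
#' ascending symbol. The list has fixed length `floor(fraction * (G - 1))`
#' for every gene with `Q > 0`; genes never called differential get an
#' empty list.
#'
#' @param map A `VoteMap`.
#' @param s Gene symbol.
#' @param fraction Friend fraction in (0, 1); default 0.05 (top 5%).
#' @param orientation `"partner"` (default) ranks by `N(g,s)/Q(s)`;
#'   `"self"` by `N(g,s)/Q(g)`.
#' @return Data frame with columns `friend`, `ratio`, `n_covotes`.
#' @export
friends_of <- function(map, s, fraction = 0.05,
                       orientation = c("partner", "self")) {
  stopifnot(inherits(map, "VoteMap"))
  orientation <- match.arg(orientation)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop2("fraction must lie in (0, 1)")
  }
  is <- map_gene_index(map, s)
  m <- floor(fraction * (length(map$genes) - 1L))
  ord <- friend_order(map, is, orientation)
  if (is.null(ord) || map$Q[[is]] == 0L) {
    return(data.frame(friend = character(), ratio = numeric(),
                      n_covotes = integer()))
  }
  take <- seq_len(m)
  data.frame(friend = map$genes[ord$idx[take]],
             ratio = ord$ratio[take],
             n_covotes = ord$n[take])
}

#' Build the full friend table
#'
#' Applies [friends_of()] to every universe gene and tallies, for each
#' gene, in how many other genes' friend lists it occurs (its global
#' friend occurrence count, the numerator of the background probability
#' used by the guilt-by-association test).
#'
#' @param map A `VoteMap`.
#' @param fraction Friend fraction in (0, 1); default 0.05.
#' @param orientation See [friends_of()].
#' @return A `FriendTable`: list with `genes`, `fraction`, `list_length`,
#'   `idx` (per-gene integer vector of friend indices, ordered), `ratio`
#'   (parallel ratios), `occurrences` (named integer vector).
#' @export
build_friend_table <- function(map, fraction = 0.05,
                               orientation = c("partner", "self")) {
  stopifnot(inherits(map, "VoteMap"))
  orientation <- match.arg(orientation)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop2("fraction must lie in (0, 1)")
  }
  G <- length(map$genes)
  m <- floor(fraction * (G - 1L))
  idx <- vector("list", G)
  ratio <- vector("list", G)
  names(idx) <- names(ratio) <- map$genes
  for (is in seq_len(G)) {
    if (map$Q[[is]] == 0L) {
      idx[[is]] <- integer()
      ratio[[is]] <- numeric()
      next
    }
    ord <- friend_order(map, is, orientation)
    take <- seq_len(m)
    idx[[is]] <- ord$idx[take]
    ratio[[is]] <- ord$ratio[take]
  }
  occurrences <- tabulate(unlist(idx, use.names = FALSE), nbins = G)
  names(occurrences) <- map$genes
  structure(
    list(genes = map$genes, fraction = fraction, list_length = m,
         idx = idx, ratio = ratio,
         occurrences = occurrences, orientation = orientation,
         Q = map$Q),
    class = "FriendTable"
  )
}

#' @export
print.FriendTable <- function(x, ...) {
  cat(sprintf(
    "<FriendTable> %d genes, top %.1f%% (%d friends per gene), %d genes with lists\n",
    length(x$genes), 100 * x$fraction, x$list_length,
    sum(lengths(x$idx) > 0L)))
  invisible(x)
}

#' Friend symbols of one gene from a built table
#'
#' @param ft A `FriendTable`.
#' @param s Gene symbol.
#' @return Character vector of friend symbols (ordered by rank).
#' @export
friend_symbols <- function(ft, s) {
  stopifnot(inherits(ft, "FriendTable"))
  i <- match(s, ft$genes)
  if (is.na(i)) stop2("gene '%s' not in the friend table", s)
  ft$genes[ft$idx[[i]]]
}

#' Global friend probability of a gene
#'
#' `p(g) = occurrences(g) / G`: the chance that gene `g` occurs in the
#' friend list of a random gene. Occurrence counting includes every list,
#' which absorbs the fact that some genes are promiscuously co-expressed.
#'
#' @param ft A `FriendTable`.
#' @param g Gene symbol.
#' @return Probability in \[0, 1\].
#' @export
global_friend_probability <- function(ft, g) {
  stopifnot(inherits(ft, "FriendTable"))
  i <- match(g, ft$genes)
  if (is.na(i)) stop2("gene '%s' not in the friend table", g)
  unname(ft$occurrences[[i]] / length(ft$genes))
}

#' Export the thresholded co-expression network
#'
#' Emits each unordered pair `(a, b)` with
#' `max(r(a|b), r(b|a)) >= cutoff` once, lexicographically ordered within
#' and across edges.
#'
#' @param map A `VoteMap`.
#' @param cutoff Ratio cutoff in (0, 1\]; default 0.8.
#' @return Data frame with columns `gene_a`, `gene_b`, `ratio` (the larger
#'   of the two orientations).
#' @export
export_network <- function(map, cutoff = 0.8) {
  stopifnot(inherits(map, "VoteMap"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop2("cutoff must lie in (0, 1]")
  }
  G <- length(map$genes)
  Q <- map$Q
  # r(a|b) = N/Q(b) per column b; max over both orientations
  keep_g <- which(Q > 0L)
  hits <- list()
  for (b in keep_g) {
    r <- map$N[, b] / Q[[b]]
    r[b] <- 0
    a <- which(r >= cutoff)
    if (length(a)) hits[[length(hits) + 1L]] <- cbind(a, b, r[a])
  }
  if (!length(hits)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      ratio = numeric()))
  }
  h <- do.call(rbind, hits)
  lo <- pmin(h[, 1L], h[, 2L])
  hi <- pmax(h[, 1L], h[, 2L])
  key <- paste(lo, hi)
  ratio <- tapply(h[, 3L], key, max)
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]
  ratio <- as.numeric(ratio[key[first]])
  ga <- map$genes[lo]; gb <- map$genes[hi]
  swap <- ga > gb
  tmp <- ga[swap]; ga[swap] <- gb[swap]; gb[swap] <- tmp
  ord <- order(ga, gb, method = "radix")
  data.frame(gene_a = ga[ord], gene_b = gb[ord], ratio = ratio[ord])
}

#' Write an edge list as 3-column TSV
#'
#' @param edges Data frame from [export_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  lines <- c("gene_a\tgene_b\tratio",
             sprintf("%s\t%s\t%.6g", edges$gene_a, edges$gene_b, edges$ratio))
  writeLines(lines, path)
  invisible(path)
}

#' Dump non-zero vote-map pairs as TSV
#'
#' One row per unordered pair with `N > 0`: `gene_a`, `gene_b`, `N`,
#' `r(a|b)`, `r(b|a)`.
#'
#' @param map A `VoteMap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_votemap_pairs <- function(map, path) {
  stopifnot(inherits(map, "VoteMap"))
  nz <- which(map$N > 0L & upper.tri(map$N), arr.ind = TRUE)
  a <- nz[, 1L]; b <- nz[, 2L]
  n <- map$N[nz]
  Qa <- map$Q[a]; Qb <- map$Q[b]
  r_ab <- ifelse(Qb > 0L, n / Qb, NA_real_)  # r(a|b) conditions on b
  r_ba <- ifelse(Qa > 0L, n / Qa, NA_real_)
  ord <- order(map$genes[a], map$genes[b], method = "radix")
  lines <- c("gene_a\tgene_b\tN\tr_a_given_b\tr_b_given_a",
             sprintf("%s\t%s\t%d\t%.6g\t%.6g",
                     map$genes[a][ord], map$genes[b][ord], n[ord],
                     r_ab[ord], r_ba[ord]))
  writeLines(lines, path)
  invisible(path)
}
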