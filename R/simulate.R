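# Planted-module synthetic expression corpora: known ground truth for every
# pipeline stage (co-regulated modules, independent background differential
# expression, replicates, missing values).

#' Parameters for a synthetic corpus
#'
#' The defaults describe the stated simulation world used throughout the
#' test suite: 1,000 genes, 50 datasets of 6 conditions with 2 replicates
#' each, one planted module of 40 genes responding jointly in 90% of
#' conditions, a 10% independent background differential rate, 2 log2
#' units of effect (a 4-fold jump, safely past the 2-fold call boundary),
#' log2 noise of 0.4 and 1% missing cells. Values are generated directly
#' on the log2 scale around `baseline_mean = 16`, keeping every dataset
#' inside the QC window (above log2(5000) ~ 12.3, below log2(2e7) ~ 24.3)
#' and below the log-transform trigger of 25.
#'
#' @param G Gene count.
#' @param D Dataset count.
#' @param conditions_per_dataset Conditions per dataset (>= 2).
#' @param replicates_per_condition Replicates per condition (>= 1).
#' @param module_sizes Integer vector of planted module sizes (possibly
#'   empty for a null corpus).
#' @param co_de_prob Probability a module responds in a given condition.
#' @param background_de_rate Per-gene per-condition probability of an
#'   independent differential jump.
#' @param effect_size_log2 Jump magnitude in log2 units (>= 1 so planted
#'   jumps clear the 2-fold cutoff by construction).
#' @param baseline_mean Log2 baseline expression level.
#' @param noise_sd Log2-scale replicate noise standard deviation.
#' @param missing_rate Probability a cell is masked missing.
#' @param n_tf Number of genes (drawn from the non-module background)
#'   labelled as transcription factors in the truth, for TF-filter tests.
#' @param linear_scale If `TRUE`, emit values on the linear scale
#'   (`2^value`) to exercise the conditional log transform.
#' @param rng_seed Integer seed; the corpus is a pure function of the
#'   parameter set including this seed.
#' @return A validated `CorpusParams` list.
#' @export
corpus_params <- function(G = 1000L, D = 50L,
                          conditions_per_dataset = 6L,
                          replicates_per_condition = 2L,
                          module_sizes = 40L,
                          co_de_prob = 0.9,
                          background_de_rate = 0.1,
                          effect_size_log2 = 2,
                          baseline_mean = 16,
                          noise_sd = 0.4,
                          missing_rate = 0.01,
                          n_tf = 0L,
                          linear_scale = FALSE,
                          rng_seed = 1L) {
  p <- list(G = as.integer(G), D = as.integer(D),
            conditions_per_dataset = as.integer(conditions_per_dataset),
            replicates_per_condition = as.integer(replicates_per_condition),
            module_sizes = as.integer(module_sizes),
            co_de_prob = co_de_prob,
            background_de_rate = background_de_rate,
            effect_size_log2 = effect_size_log2,
            baseline_mean = baseline_mean,
            noise_sd = noise_sd,
            missing_rate = missing_rate,
            n_tf = as.integer(n_tf),
            linear_scale = isTRUE(linear_scale),
            rng_seed = as.integer(rng_seed))
  if (p$G < 2L) stop2("G must be >= 2")
  if (p$D < 1L) stop2("D must be >= 1")
  if (p$conditions_per_dataset < 2L) stop2("conditions_per_dataset must be >= 2")
  if (p$replicates_per_condition < 1L) stop2("replicates_per_condition must be >= 1")
  if (any(p$module_sizes < 2L)) stop2("each module needs >= 2 genes")
  if (sum(p$module_sizes) > p$G) stop2("sum(module_sizes) exceeds G")
  if (!is_prob(p$co_de_prob)) stop2("co_de_prob must lie in [0, 1]")
  if (!is_prob(p$background_de_rate)) stop2("background_de_rate must lie in [0, 1]")
  if (!is_prob(p$missing_rate)) stop2("missing_rate must lie in [0, 1]")
  if (p$effect_size_log2 < 1) stop2("effect_size_log2 must be >= 1 (2-fold)")
  if (p$noise_sd < 0) stop2("noise_sd must be >= 0")
  if (p$n_tf > p$G - sum(p$module_sizes)) stop2("n_tf exceeds background size")
  structure(p, class = "CorpusParams")
}

synthetic_symbols <- function(G) sprintf("G%06d", seq_len(G))

#' Simulate a multi-dataset expression corpus with planted modules
#'
#' Per dataset each gene gets a baseline level (`baseline_mean` plus a
#' per-gene, per-dataset offset). Per condition, each planted module
#' jointly shifts by `+/- effect_size_log2` with probability `co_de_prob`
#' (one coin and one shared sign per module per condition), while each
#' background gene shifts independently with probability
#' `background_de_rate`. Replicate values add Gaussian noise; cells are
#' masked missing with `missing_rate`. The result is fully determined by
#' the parameter set.
#'
#' @param params A [corpus_params()] object.
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `truth` (a `PlantedTruth`: `module_members` list of symbol vectors,
#'   `background` symbols, `tfs` symbols).
#' @export
simulate_corpus <- function(params = corpus_params()) {
  stopifnot(inherits(params, "CorpusParams"))
  p <- params
  genes <- synthetic_symbols(p$G)
  n_mod <- sum(p$module_sizes)
  module_members <- list()
  at <- 0L
  for (m in seq_along(p$module_sizes)) {
    module_members[[m]] <- genes[(at + 1L):(at + p$module_sizes[[m]])]
    at <- at + p$module_sizes[[m]]
  }
  background <- genes[setdiff(seq_len(p$G), seq_len(n_mod))]
  datasets <- with_rng_seed(p$rng_seed, {
    tfs <- if (p$n_tf > 0L) sort(sample(background, p$n_tf)) else character()
    ds <- lapply(seq_len(p$D), function(d) simulate_dataset(p, d, genes))
    list(ds = ds, tfs = tfs)
  })
  truth <- structure(
    list(module_members = module_members, background = background,
         tfs = datasets$tfs),
    class = "PlantedTruth"
  )
  list(datasets = datasets$ds, truth = truth)
}

# One dataset: consumes the ambient RNG stream (already seeded).
simulate_dataset <- function(p, d, genes) {
  C <- p$conditions_per_dataset
  R <- p$replicates_per_condition
  n_mod_genes <- sum(p$module_sizes)
  baseline <- p$baseline_mean + stats::rnorm(p$G, sd = 1)
  # per-condition shift matrix (G x C), log2 units
  shift <- matrix(0, p$G, C)
  at <- 0L
  for (m in seq_along(p$module_sizes)) {
    rows <- (at + 1L):(at + p$module_sizes[[m]])
    at <- at + p$module_sizes[[m]]
    fires <- stats::runif(C) < p$co_de_prob
    signs <- sample(c(-1, 1), C, replace = TRUE)
    shift[rows, ] <- rep(ifelse(fires, signs * p$effect_size_log2, 0),
                         each = length(rows))
  }
  bg_rows <- setdiff(seq_len(p$G), seq_len(n_mod_genes))
  if (length(bg_rows)) {
    fires <- matrix(stats::runif(length(bg_rows) * C) < p$background_de_rate,
                    length(bg_rows), C)
    signs <- matrix(sample(c(-1, 1), length(bg_rows) * C, replace = TRUE),
                    length(bg_rows), C)
    shift[bg_rows, ] <- ifelse(fires, signs * p$effect_size_log2, 0)
  }
  cond_level <- baseline + shift  # recycles baseline down columns
  values <- matrix(NA_real_, p$G, C * R)
  cond_of <- character(C * R)
  sample_ids <- character(C * R)
  col <- 0L
  for (cc in seq_len(C)) {
    for (r in seq_len(R)) {
      col <- col + 1L
      noise <- if (p$noise_sd > 0) stats::rnorm(p$G, sd = p$noise_sd) else 0
      values[, col] <- cond_level[, cc] + noise
      cond_of[[col]] <- sprintf("cond%02d", cc)
      sample_ids[[col]] <- sprintf("ds%03d_c%02d_r%02d", d, cc, r)
    }
  }
  if (p$missing_rate > 0) {
    mask <- stats::runif(length(values)) < p$missing_rate
    values[mask] <- NA_real_
  }
  if (p$linear_scale) values <- 2^values
  dimnames(values) <- list(genes, sample_ids)
  expression_dataset(sprintf("sim%03d", d), values,
                     stats::setNames(cond_of, sample_ids))
}

#' Simulate a matched null corpus (no planted modules)
#'
#' Identical to [simulate_corpus()] with `module_sizes` forced empty:
#' only independent background differential expression remains. Used for
#' specificity and randomization-calibration tests.
#'
#' @param params A [corpus_params()] object; its `module_sizes` are
#'   ignored.
#' @return List of [expression_dataset()] objects.
#' @export
null_corpus <- function(params = corpus_params()) {
  stopifnot(inherits(params, "CorpusParams"))
  p <- unclass(params)
  p$module_sizes <- integer()
  p <- do.call(corpus_params, p)
  simulate_corpus(p)$datasets
}

#' Write a simulated corpus to disk in the TSV dialect
#'
#' Writes one expression matrix and one condition map per dataset, a
#' module-membership truth file, the TF list (if any), the universe list
#' and a corpus manifest, plus the parameters as a flat config file.
#'
#' @param sim Result of [simulate_corpus()].
#' @param dir Output directory (created if needed).
#' @param params The [corpus_params()] used (stored for reproducibility).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(sim, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(dir, "manifest.tsv")
  rows <- character()
  for (ds in sim$datasets) {
    ep <- file.path(dir, paste0(ds$dataset_id, "_expr.tsv"))
    cp <- file.path(dir, paste0(ds$dataset_id, "_conditions.tsv"))
    write_expression_matrix(ds, ep)
    writeLines(paste(names(ds$condition_of), ds$condition_of, sep = "\t"), cp)
    rows <- c(rows, paste(ds$dataset_id, basename(ep), basename(cp), sep = "\t"))
  }
  writeLines(c("dataset_id\texpression_path\tcondition_map_path", rows), manifest)
  truth <- sim$truth
  mod_rows <- unlist(lapply(seq_along(truth$module_members), function(m) {
    paste(sprintf("module%02d", m), truth$module_members[[m]], sep = "\t")
  }))
  writeLines(c("module\tgene", mod_rows),
             file.path(dir, "truth_modules.tsv"))
  writeLines(sort(c(unlist(truth$module_members), truth$background)),
             file.path(dir, "universe.txt"))
  if (length(truth$tfs)) writeLines(truth$tfs, file.path(dir, "tfs.txt"))
  if (!is.null(params)) {
    write_flat_config(unclass(params), file.path(dir, "params.cfg"))
  }
  invisible(manifest)
}
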