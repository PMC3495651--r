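# Orchestration: run configuration, corpus manifests, the end-to-end
# pipeline (read -> preprocess -> vote map -> friend table -> ranking) and
# result serialization.

#' Run configuration
#'
#' Collects every tunable threshold of the pipeline with the method's
#' canonical defaults: a 2-fold differential cutoff, top-5% friend lists,
#' a 1e-6 reporting cutoff, QC thresholds (log-transform trigger 25,
#' signal window log2(5000)..log2(2e7), 90% annotation coverage) and an
#' 0.8 ratio cutoff for network export.
#'
#' @param fold_threshold Fold-change cutoff (default 2).
#' @param friend_fraction Friend-list fraction (default 0.05).
#' @param alpha Reporting cutoff for the significance flag (default 1e-6).
#' @param log_trigger,low_signal,out_of_range,min_coverage QC thresholds;
#'   see [qc_defaults()].
#' @param ratio_cutoff Network-export ratio cutoff (default 0.8).
#' @param ratio_orientation `"partner"` or `"self"`; see [friends_of()].
#' @param rng_seed Integer seed for any randomized step.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(fold_threshold = 2,
                       friend_fraction = 0.05,
                       alpha = 1e-6,
                       log_trigger = 25,
                       low_signal = 5000,
                       out_of_range = 2e7,
                       min_coverage = 0.90,
                       ratio_cutoff = 0.8,
                       ratio_orientation = c("partner", "self"),
                       rng_seed = 1L) {
  ratio_orientation <- match.arg(ratio_orientation)
  cfg <- list(fold_threshold = fold_threshold,
              friend_fraction = friend_fraction,
              alpha = alpha,
              log_trigger = log_trigger,
              low_signal = low_signal,
              out_of_range = out_of_range,
              min_coverage = min_coverage,
              ratio_cutoff = ratio_cutoff,
              ratio_orientation = ratio_orientation,
              rng_seed = as.integer(rng_seed))
  if (cfg$fold_threshold < 1) stop2("fold_threshold must be >= 1")
  if (cfg$friend_fraction <= 0 || cfg$friend_fraction >= 1) {
    stop2("friend_fraction must lie in (0, 1)")
  }
  if (!is_prob(cfg$alpha)) stop2("alpha must lie in [0, 1]")
  if (cfg$ratio_cutoff <= 0 || cfg$ratio_cutoff > 1) {
    stop2("ratio_cutoff must lie in (0, 1]")
  }
  structure(cfg, class = "RunConfig")
}

#' Read/write a flat key=value config file
#'
#' @param path Path to the config file (`key = value`, one per line, `#`
#'   comments).
#' @return For `read_flat_config`, a named list with numeric values
#'   coerced where possible.
#' @export
read_flat_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: %s", path)
  lines <- trim_ws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop2("%s:%d: expected 'key = value'", path, bad[[1L]])
  keys <- trim_ws(vapply(kv, `[[`, "", 2L))
  vals <- trim_ws(vapply(kv, `[[`, "", 3L))
  out <- lapply(vals, function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  stats::setNames(out, keys)
}

#' @rdname read_flat_config
#' @param config Named list of scalar values.
#' @export
write_flat_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.numeric(v) && length(v) > 1L) paste(v, collapse = ",")
    else if (is.numeric(v)) sprintf("%.17g", v)
    else paste(as.character(v), collapse = ",")
  }, "")
  writeLines(paste(names(config), fmt, sep = " = "), path)
  invisible(path)
}

#' Read a corpus manifest
#'
#' TSV with header and columns `dataset_id`, `expression_path`,
#' `condition_map_path` and optionally `probe_map_path`; relative paths
#' are resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return Data frame with one row per dataset.
#' @export
read_corpus_manifest <- function(path) {
  if (!file.exists(path)) stop2("manifest not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "expression_path", "condition_map_path")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop2("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  if (!nrow(tab)) stop2("%s: empty manifest", path)
  base <- dirname(path)
  resolve <- function(p) ifelse(nzchar(p) & !grepl("^/", p),
                                file.path(base, p), p)
  tab$expression_path <- resolve(tab$expression_path)
  tab$condition_map_path <- resolve(tab$condition_map_path)
  if ("probe_map_path" %in% names(tab)) {
    tab$probe_map_path <- resolve(tab$probe_map_path)
  }
  tab
}

#' Load a corpus listed in a manifest
#'
#' Reads each expression matrix and its condition map; when a probe map is
#' given, collapses probes to symbols and records the annotation coverage.
#'
#' @param manifest Data frame from [read_corpus_manifest()].
#' @return List with `datasets` (list of [expression_dataset()]) and
#'   `coverages` (numeric vector, 1 where no probe map applies).
#' @export
load_corpus <- function(manifest) {
  datasets <- vector("list", nrow(manifest))
  coverages <- rep(1, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$dataset_id[[i]]
    cond <- tryCatch(read_condition_map(manifest$condition_map_path[[i]]),
                     error = function(e) stop2("[load_corpus:%s] %s", id,
                                               conditionMessage(e)))
    ds <- tryCatch(
      read_expression_matrix(manifest$expression_path[[i]],
                             dataset_id = id, condition_of = cond),
      error = function(e) stop2("[load_corpus:%s] %s", id, conditionMessage(e)))
    pm_path <- if ("probe_map_path" %in% names(manifest))
      manifest$probe_map_path[[i]] else ""
    if (!is.na(pm_path) && nzchar(pm_path)) {
      pm <- read_probe_map(pm_path)
      coverages[[i]] <- probe_coverage(ds, pm)
      ds <- collapse_probes(ds, pm)
    }
    datasets[[i]] <- ds
  }
  list(datasets = datasets, coverages = coverages)
}

#' Run the full pipeline
#'
#' Reads the corpus (or accepts in-memory datasets), preprocesses it,
#' builds the vote map over the universe, derives the friend table, ranks
#' every gene against the seed list and optionally restricts to
#' transcription factors. When `out_dir` is given, writes the ranked
#' tables, the network edge list, the QC audit log and a run-metadata
#' file (effective config plus input digests).
#'
#' @param config A [run_config()].
#' @param seed A `GeneList` of seed symbols.
#' @param universe A `GeneList` fixing the gene universe.
#' @param manifest_path Path to a corpus manifest, or `NULL` when
#'   `datasets` is supplied directly.
#' @param datasets Optional list of [expression_dataset()] objects.
#' @param tfs Optional `GeneList` of transcription factors.
#' @param out_dir Optional output directory.
#' @return List with `gba` (the `GbaTable`), `tf_gba` (TF-restricted table
#'   or `NULL`), `map`, `friend_table`, `qc`, and `paths` of written
#'   artifacts.
#' @export
run_pipeline <- function(config, seed, universe, manifest_path = NULL,
                         datasets = NULL, tfs = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.null(datasets)) {
    if (is.null(manifest_path)) stop2("supply manifest_path or datasets")
    corpus <- load_corpus(read_corpus_manifest(manifest_path))
  } else {
    corpus <- list(datasets = datasets, coverages = rep(1, length(datasets)))
  }
  thresholds <- list(log_trigger = config$log_trigger,
                     low_signal = config$low_signal,
                     out_of_range = config$out_of_range,
                     min_coverage = config$min_coverage)
  pre <- preprocess_corpus(corpus$datasets, corpus$coverages, thresholds)
  if (!length(pre$matrices)) stop2("[preprocess] no dataset survived QC")
  map <- build_map(pre$matrices, universe, config$fold_threshold)
  ft <- build_friend_table(map, config$friend_fraction,
                           config$ratio_orientation)
  gba <- rank_candidates(ft, seed, config$alpha)
  tf_gba <- if (!is.null(tfs)) filter_tfs(gba, tfs) else NULL
  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      gba = write_results(gba, file.path(out_dir, "gba.tsv")),
      qc = write_qc_audit(pre$qc, file.path(out_dir, "qc_audit.tsv")),
      network = write_network(export_network(map, config$ratio_cutoff),
                              file.path(out_dir, "network.tsv"))
    )
    if (!is.null(tf_gba)) {
      paths <- c(paths,
                 tf_gba = write_results(tf_gba, file.path(out_dir, "gba_tf.tsv")))
    }
    meta <- c(unclass(config),
              list(universe_size = length(universe$symbols),
                   seed_name = if (inherits(seed, "GeneList")) seed$name else "seed",
                   n_datasets_in = length(corpus$datasets),
                   n_datasets_kept = length(pre$matrices),
                   x_comparisons = map$x,
                   output_digests = paste(
                     names(paths),
                     unname(tools::md5sum(unname(paths))),
                     sep = ":", collapse = ";")))
    write_flat_config(meta, file.path(out_dir, "run_metadata.cfg"))
    paths <- c(paths, metadata = file.path(out_dir, "run_metadata.cfg"))
  }
  list(gba = gba, tf_gba = tf_gba, map = map, friend_table = ft,
       qc = pre$qc, paths = paths)
}

#' Write a ranked table as TSV
#'
#' Columns `rank`, `gene`, `k`, `n`, `p_background`, `pvalue`,
#' `significant`; p-values in scientific notation with three significant
#' digits (they survive a re-parse), LF line endings, trailing newline.
#'
#' @param table A `GbaTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(inherits(table, "GbaTable"))
  lines <- c("rank\tgene\tk\tn\tp_background\tpvalue\tsignificant",
             sprintf("%d\t%s\t%d\t%d\t%.3e\t%.3e\t%s",
                     table$rank, table$gene, table$k, table$n,
                     table$p_background, table$pvalue,
                     ifelse(table$significant, "TRUE", "FALSE")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read back a ranked table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return Data frame with the table's columns.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
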