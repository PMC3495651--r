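# Dataset-level QC and reduction: conditional log2 transform, value-range
# filters, annotation-coverage filter, replicate averaging.

#' Default QC thresholds
#'
#' * `log_trigger` (25): any finite value above this marks the dataset as
#'   linear-scale, triggering a log2 transform of every cell.
#' * `low_signal` (5000): a dataset whose maximum is not above
#'   `log2(5000)` (~12.29) is discarded as low signal.
#' * `out_of_range` (2e7): any value above `log2(2e7)` (~24.25) discards
#'   the dataset as containing nonsense values.
#' * `min_coverage` (0.90): minimum fraction of probes with a gene symbol.
#'
#' @return Named list of the four thresholds.
#' @export
qc_defaults <- function() {
  list(log_trigger = 25, low_signal = 5000, out_of_range = 2e7,
       min_coverage = 0.90)
}

#' Conditionally log2-transform a dataset
#'
#' Datasets containing any finite value above `log_trigger` (default 25)
#' are assumed to be on the linear scale and every finite value is replaced
#' by its log2; non-positive values become missing. Datasets already on the
#' log scale are returned unchanged, so the operation is idempotent once
#' the post-transform maximum is at or below the trigger.
#'
#' @param dataset An [expression_dataset()].
#' @param log_trigger Strict threshold above which the transform fires.
#' @return An [expression_dataset()] on the log2 scale.
#' @export
maybe_log_transform <- function(dataset, log_trigger = qc_defaults()$log_trigger) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  # an all-missing dataset has nothing to transform; QC removes it later
  # (its maximum cannot clear the low-signal rule)
  if (!any(is.finite(v))) return(dataset)
  if (max(v, na.rm = TRUE) <= log_trigger) return(dataset)
  nonpos <- !is.na(v) & v <= 0
  if (any(nonpos)) {
    message(sprintf("dataset '%s': %d non-positive value(s) set to missing during log2 transform",
                    dataset$dataset_id, sum(nonpos)))
    v[nonpos] <- NA_real_
  }
  v <- log2(v)
  expression_dataset(dataset$dataset_id, v, dataset$condition_of)
}

#' Quality-control filter for one dataset
#'
#' Applies the corpus selection rules after [maybe_log_transform()]:
#' a dataset is dropped when its maximum is not above `log2(low_signal)`
#' (`low_signal` rule), when any value exceeds `log2(out_of_range)`
#' (`out_of_range` rule), when fewer than `min_coverage` of its probes
#' carried a gene symbol (`low_annotation_coverage` rule), or when it has
#' fewer than two distinct conditions so no comparison is possible
#' (`too_few_conditions` rule). Reasons accumulate.
#'
#' @param dataset An [expression_dataset()] (log2 scale).
#' @param probe_coverage Fraction of probes annotated with a symbol, from
#'   [probe_coverage()]; defaults to 1 (symbol-keyed input).
#' @param thresholds List as returned by [qc_defaults()].
#' @return A `QcReport`: list with `dataset_id`, `kept`, `reasons`.
#' @export
qc_filter <- function(dataset, probe_coverage = 1,
                      thresholds = qc_defaults()) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  reasons <- character()
  finite <- v[is.finite(v)]
  if (!length(finite) || max(finite) <= log2(thresholds$low_signal)) {
    reasons <- c(reasons, "low_signal")
  }
  if (length(finite) && max(finite) > log2(thresholds$out_of_range)) {
    reasons <- c(reasons, "out_of_range")
  }
  if (probe_coverage < thresholds$min_coverage) {
    reasons <- c(reasons, "low_annotation_coverage")
  }
  if (length(unique(dataset$condition_of)) < 2L) {
    reasons <- c(reasons, "too_few_conditions")
  }
  structure(
    list(dataset_id = dataset$dataset_id, kept = length(reasons) == 0L,
         reasons = reasons),
    class = "QcReport"
  )
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("<QcReport> %s: %s%s\n", x$dataset_id,
              if (x$kept) "kept" else "removed",
              if (x$kept) "" else paste0(" (", paste(x$reasons, collapse = "; "), ")")))
  invisible(x)
}

#' Write QC reports as a TSV audit log
#'
#' @param reports List of `QcReport` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_audit <- function(reports, path) {
  lines <- c("dataset_id\tkept\treasons",
             vapply(reports, function(r) {
               sprintf("%s\t%s\t%s", r$dataset_id,
                       if (r$kept) "TRUE" else "FALSE",
                       paste(r$reasons, collapse = ";"))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Average replicates into a condition matrix
#'
#' Samples sharing a condition label are averaged per gene, ignoring
#' missing replicate values. A gene that is missing in a condition with a
#' single replicate is removed from the dataset entirely (its value cannot
#' be recovered); in multi-replicate conditions a cell stays missing only
#' when every replicate is missing.
#'
#' @param dataset An [expression_dataset()] that passed [qc_filter()].
#' @return A `ConditionMatrix`: list with `dataset_id`, `values` (genes x
#'   conditions), `replicate_counts`.
#' @export
average_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  cond <- dataset$condition_of
  conds <- unique(cond)
  v <- dataset$values
  finite <- !is.na(v)
  means <- matrix(NA_real_, nrow(v), length(conds),
                  dimnames = list(rownames(v), conds))
  reps <- integer(length(conds))
  names(reps) <- conds
  for (j in seq_along(conds)) {
    cols <- which(cond == conds[[j]])
    reps[[j]] <- length(cols)
    sub <- v[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    m <- s / n
    m[n == 0L] <- NA_real_
    means[, j] <- m
  }
  # single-replicate condition with a missing value: drop the gene row
  single <- conds[reps == 1L]
  if (length(single)) {
    drop <- rowSums(is.na(means[, single, drop = FALSE])) > 0L
    means <- means[!drop, , drop = FALSE]
  }
  structure(
    list(dataset_id = dataset$dataset_id, values = means,
         replicate_counts = reps),
    class = "ConditionMatrix"
  )
}

#' @export
print.ConditionMatrix <- function(x, ...) {
  cat(sprintf("<ConditionMatrix> %s: %d genes x %d conditions\n",
              x$dataset_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Preprocess a corpus of datasets
#'
#' Runs [maybe_log_transform()], [qc_filter()] and [average_replicates()]
#' over a list of datasets, returning the surviving condition matrices and
#' the full QC audit.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param coverages Optional numeric vector of per-dataset probe coverages
#'   (parallel to `datasets`); defaults to 1 for all.
#' @param thresholds List as returned by [qc_defaults()].
#' @return List with `matrices` (list of `ConditionMatrix`) and `qc`
#'   (list of `QcReport`).
#' @export
preprocess_corpus <- function(datasets, coverages = NULL,
                              thresholds = qc_defaults()) {
  if (!length(datasets)) stop2("empty corpus")
  coverages <- coverages %||% rep(1, length(datasets))
  qc <- vector("list", length(datasets))
  cms <- list()
  for (i in seq_along(datasets)) {
    ds <- maybe_log_transform(datasets[[i]], thresholds$log_trigger)
    rep_i <- qc_filter(ds, coverages[[i]], thresholds)
    qc[[i]] <- rep_i
    if (rep_i$kept) cms[[length(cms) + 1L]] <- average_replicates(ds)
  }
  list(matrices = cms, qc = qc)
}
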