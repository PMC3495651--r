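# Reading and validating expression matrices, probe maps, condition maps and
# gene lists; collapsing probe-level rows to gene symbols.

#' Construct an expression dataset
#'
#' An `ExpressionDataset` holds one genes x samples matrix of expression
#' values (log2 scale after preprocessing) together with a sample ->
#' condition assignment. Row names are gene symbols (or probe ids before
#' [collapse_probes()]), column names are sample ids.
#'
#' @param dataset_id Character scalar identifying the dataset.
#' @param values Numeric matrix with unique row names (genes/probes) and
#'   unique column names (samples). `NA` marks missing cells.
#' @param condition_of Named character vector mapping every sample id in
#'   `colnames(values)` to a condition label.
#' @return An object of class `ExpressionDataset`.
#' @export
expression_dataset <- function(dataset_id, values, condition_of) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop2("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop2("`values` must have row names (genes) and column names (samples)")
  }
  if (anyDuplicated(rownames(values))) {
    stop2("duplicate row ids in dataset '%s'", dataset_id)
  }
  if (anyDuplicated(colnames(values))) {
    stop2("duplicate sample ids in dataset '%s'", dataset_id)
  }
  if (ncol(values) == 0L) stop2("dataset '%s' has zero samples", dataset_id)
  missing_cond <- setdiff(colnames(values), names(condition_of))
  if (length(missing_cond)) {
    stop2("dataset '%s': no condition label for sample(s) %s",
          dataset_id, paste(missing_cond, collapse = ", "))
  }
  structure(
    list(
      dataset_id = as.character(dataset_id),
      values = values,
      condition_of = condition_of[colnames(values)]
    ),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "<ExpressionDataset> %s: %d genes x %d samples, %d conditions, %.1f%% missing\n",
    x$dataset_id, nrow(x$values), ncol(x$values),
    length(unique(x$condition_of)),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Read a tab-separated expression matrix
#'
#' Expects the on-disk dialect: a header line `gene<TAB>sample1<TAB>...`,
#' then one row per gene/probe with the row id in the first column. Empty
#' cells, `NA` and `NaN` are read as missing. No transformation is applied;
#' values are kept exactly as printed.
#'
#' @param path Path to the TSV file.
#' @param dataset_id Dataset identifier; defaults to the file name without
#'   extension.
#' @param condition_of Optional named character vector (sample -> condition).
#'   When omitted every sample becomes its own condition; attach the real
#'   map with [read_condition_map()].
#' @return An [expression_dataset()].
#' @seealso [write_expression_matrix()] for the inverse operation.
#' @export
read_expression_matrix <- function(path, dataset_id = NULL, condition_of = NULL) {
  if (!file.exists(path)) stop2("expression matrix not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop2("%s: empty file", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop2("%s:1: malformed header, need at least one sample column", path)
  }
  samples <- trim_ws(header[-1L])
  if (anyDuplicated(samples)) {
    stop2("%s:1: duplicated sample id(s) in header: %s", path,
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  body <- lines[-1L]
  if (!length(body)) stop2("%s: no data rows", path)
  # rectangularity is judged on tab counts: trailing empty cells are legal
  # (missing values) but strsplit drops them, so pad after the check
  ntabs <- lengths(regmatches(body, gregexpr("\t", body, fixed = TRUE)))
  bad_rows <- which(ntabs != length(header) - 1L)
  if (length(bad_rows)) {
    stop2("%s:%d: row has %d fields, expected %d", path,
          bad_rows[[1L]] + 1L, ntabs[[bad_rows[[1L]]]] + 1L, length(header))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    if (length(f) < length(header)) c(f, rep("", length(header) - length(f))) else f
  })
  ids <- trim_ws(vapply(fields, `[[`, "", 1L))
  if (anyDuplicated(ids)) {
    stop2("%s: duplicated row id(s): %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- unlist(lapply(fields, `[`, -1L), use.names = FALSE)
  parsed <- parse_cells(cells)
  if (any(parsed$bad)) {
    first <- which(parsed$bad)[[1L]]
    row <- (first - 1L) %/% length(samples) + 1L
    stop2("%s:%d: non-numeric cell '%s'", path, row + 1L, cells[[first]])
  }
  values <- matrix(parsed$values, nrow = length(ids), ncol = length(samples),
                   byrow = TRUE, dimnames = list(ids, samples))
  if (is.null(condition_of)) {
    condition_of <- stats::setNames(samples, samples)
  }
  expression_dataset(
    dataset_id = dataset_id %||% sub("\\.[^.]*$", "", basename(path)),
    values = values,
    condition_of = condition_of
  )
}

#' Write an expression matrix in the TSV dialect
#'
#' Missing cells are written as empty fields. Finite values are written with
#' full precision (`%.17g`) so that a write/read round trip is bit exact.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  cells <- sprintf("%.17g", v)
  cells[is.na(v)] <- ""
  body <- apply(matrix(cells, nrow = nrow(v)), 1L, paste, collapse = "\t")
  lines <- c(
    paste(c("gene", colnames(v)), collapse = "\t"),
    paste(rownames(v), body, sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe -> gene-symbol map
#'
#' Two-column TSV (probe id, gene symbol). Probes mapping to an empty symbol
#' are treated as unannotated and dropped from the map.
#'
#' @param path Path to the TSV file.
#' @return A named character vector (names = probe ids, values = symbols).
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop2("probe map not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  probes <- trim_ws(vapply(fields, `[[`, "", 1L))
  symbols <- trim_ws(vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", ""))
  keep <- nzchar(symbols)
  map <- stats::setNames(symbols[keep], probes[keep])
  dup <- duplicated(names(map))
  if (any(dup)) {
    conflict <- tapply(map, names(map), function(s) length(unique(s)) > 1L)
    if (any(conflict)) {
      stop2("%s: probe(s) mapped to conflicting symbols: %s", path,
            paste(names(conflict)[conflict], collapse = ", "))
    }
    map <- map[!dup]
  }
  map
}

#' Fraction of a dataset's probes covered by a probe map
#'
#' @param dataset An [expression_dataset()] keyed by probe id.
#' @param probe_map Named character vector from [read_probe_map()].
#' @return Fraction in \[0, 1\] of the dataset's rows with a symbol.
#' @export
probe_coverage <- function(dataset, probe_map) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  mean(rownames(dataset$values) %in% names(probe_map))
}

#' Collapse probe-level rows to gene symbols
#'
#' Probes sharing a symbol are averaged cell-wise (arithmetic mean over the
#' finite probe values; a cell is missing only when every contributing probe
#' is missing). Probes without a symbol entry are dropped.
#'
#' @param dataset An [expression_dataset()] whose rows are probe ids.
#' @param probe_map Named character vector (probe id -> symbol).
#' @return An [expression_dataset()] keyed by gene symbol.
#' @export
collapse_probes <- function(dataset, probe_map) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (length(probe_map) == 0L) stop2("probe map is empty")
  v <- dataset$values
  mapped <- rownames(v) %in% names(probe_map)
  if (!any(mapped)) stop2("dataset '%s': no probe maps to a symbol", dataset$dataset_id)
  v <- v[mapped, , drop = FALSE]
  sym <- unname(probe_map[rownames(v)])
  finite <- !is.na(v)
  vz <- v
  vz[!finite] <- 0
  sums <- rowsum(vz, sym)
  counts <- rowsum(finite + 0, sym)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_dataset(dataset$dataset_id, out, dataset$condition_of)
}

#' Read a sample -> condition map
#'
#' Two-column TSV (sample id, condition label). A sample listed twice with
#' the same label is accepted once; conflicting labels are an error.
#'
#' @param path Path to the TSV file.
#' @return Named character vector (names = sample ids, values = conditions).
#' @export
read_condition_map <- function(path) {
  if (!file.exists(path)) stop2("condition map not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop2("%s: empty condition map", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 2L)
  if (length(short)) stop2("%s:%d: expected two tab-separated columns", path, short[[1L]])
  ids <- trim_ws(vapply(fields, `[[`, "", 1L))
  labels <- trim_ws(vapply(fields, `[[`, "", 2L))
  conflict <- tapply(labels, ids, function(l) length(unique(l)) > 1L)
  if (any(conflict)) {
    stop2("%s: sample(s) with conflicting condition labels: %s", path,
          paste(names(conflict)[conflict], collapse = ", "))
  }
  keep <- !duplicated(ids)
  stats::setNames(labels[keep], ids[keep])
}

#' Read a gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are ignored;
#' duplicates are removed keeping first occurrence (order preserved).
#'
#' @param path Path to the list file.
#' @param name List name; defaults to the file name without extension.
#' @return A `GeneList`: list with elements `name` and `symbols`.
#' @export
read_gene_list <- function(path, name = NULL) {
  if (!file.exists(path)) stop2("gene list not found: %s", path)
  lines <- trim_ws(readLines(path, warn = FALSE))
  symbols <- lines[nzchar(lines) & !startsWith(lines, "#")]
  symbols <- symbols[!duplicated(symbols)]
  if (!length(symbols)) stop2("%s: gene list empty after filtering", path)
  gene_list(symbols, name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a gene list in memory
#'
#' @param symbols Character vector of gene symbols; duplicates removed,
#'   order preserved.
#' @param name List name.
#' @return A `GeneList`.
#' @export
gene_list <- function(symbols, name = "gene_list") {
  symbols <- trim_ws(as.character(symbols))
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(symbols)]
  if (!length(symbols)) stop2("gene list '%s' is empty", name)
  structure(list(name = name, symbols = symbols), class = "GeneList")
}

#' @export
print.GeneList <- function(x, ...) {
  cat(sprintf("<GeneList> %s: %d symbols\n", x$name, length(x$symbols)))
  invisible(x)
}

#' @export
length.GeneList <- function(x) length(x$symbols)

#' Write a gene list (one symbol per line)
#'
#' @param gl A `GeneList`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(gl, path) {
  stopifnot(inherits(gl, "GeneList"))
  writeLines(gl$symbols, path)
  invisible(path)
}
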