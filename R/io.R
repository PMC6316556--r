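# Readers/writers for count, design and result tables, plus the
# mean-count gene filter applied before fitting.

.sep_for <- function(path, format) {
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  switch(format, tsv = "\t", csv = ",",
         stop(sprintf("unknown table format '%s'", format), call. = FALSE))
}

.validate_counts <- function(m) {
  if (is.null(rownames(m)) || any(!nzchar(rownames(m)))) {
    stop("count table must have gene ids as row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene ids in count table: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids in count table: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: gene '%s', sample '%s' (value %s)",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
      format(m[bad[1, 1], bad[1, 2]])), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' Read a gene-by-sample count table
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' tab-separated by default, comma-separated for `.csv` files or with
#' `format = "csv"`. All counts must be non-negative integers; duplicate
#' gene or sample ids and negative or fractional values raise descriptive
#' errors naming the offending cell.
#'
#' @param path path to the table.
#' @param format `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return integer matrix with gene ids as row names, sample ids as columns.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path, format),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2) {
    stop("count table needs a gene-id column plus at least one sample column",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    stop("count columns must be numeric", call. = FALSE)
  }
  rownames(m) <- as.character(df[[1]])
  .validate_counts(m)
}

#' Write a count table
#'
#' @param counts integer matrix (genes x samples).
#' @param path output path.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = .sep_for(path, format),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validate_design <- function(design) {
  need <- c("sample", "fraction", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns: sample, fraction, replicate",
         call. = FALSE)
  }
  if (!"condition" %in% names(design)) design$condition <- "all"
  design$sample <- as.character(design$sample)
  design$fraction <- as.character(design$fraction)
  design$replicate <- as.character(design$replicate)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  bad <- setdiff(unique(design$fraction), FRACTIONS)
  if (length(bad) > 0) {
    stop("unknown fraction label(s) in design: ",
         paste(bad, collapse = ", "),
         " (expected input/eluate/supernatant)", call. = FALSE)
  }
  design[, c("sample", "fraction", "replicate", "condition")]
}

#' Read a sample design table
#'
#' Columns `sample`, `fraction` (input/eluate/supernatant), `replicate` and
#' optionally `condition` (defaults to `"all"`).
#'
#' @inheritParams read_counts
#' @return a validated design `data.frame`.
#' @export
read_design <- function(path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path, format),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  .validate_design(df)
}

#' Write a sample design table
#' @param design design `data.frame`.
#' @inheritParams write_counts
#' @export
write_design <- function(design, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  utils::write.table(design, path, sep = .sep_for(path, format),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spike-in identifiers (one id per line)
#' @param path text file of spike-in row ids, one per line.
#' @return character vector of ids.
#' @export
read_spikeins <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0) stop("no spike-in ids found in ", path, call. = FALSE)
  unique(ids)
}

#' Filter genes by mean read count in the reference samples
#'
#' Keeps exactly the genes whose mean count across the mode's reference
#' samples is strictly greater than `threshold` (default 100): the input
#' samples in the spike-in-free mode, or all eluate and supernatant samples
#' in the spike-in mode. Spike-in rows are exempt (they face the spike-in
#' minimum-count rule instead). Filtering is idempotent.
#'
#' @param counts integer count matrix.
#' @param design sample design `data.frame`.
#' @param mode `"no_spikeins"` or `"spikeins"`.
#' @param threshold strict mean-count cutoff (genes at exactly the
#'   threshold are dropped).
#' @param spikeins optional character vector of spike-in row ids to exempt.
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, design, mode = c("no_spikeins", "spikeins"),
                         threshold = 100, spikeins = NULL) {
  mode <- match.arg(mode)
  design <- .validate_design(design)
  ref <- if (mode == "no_spikeins") {
    design$sample[design$fraction == "input"]
  } else {
    design$sample[design$fraction %in% c("eluate", "supernatant")]
  }
  if (length(ref) == 0) {
    stop(sprintf("no reference samples for mode '%s' in design", mode),
         call. = FALSE)
  }
  missing <- setdiff(ref, colnames(counts))
  if (length(missing) > 0) {
    stop("design samples missing from count table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  is_spike <- rownames(counts) %in% spikeins
  keep <- rowMeans(counts[, ref, drop = FALSE]) > threshold
  out <- counts[keep | is_spike, , drop = FALSE]
  if (sum(keep & !is_spike) == 0) {
    stop(sprintf(
      "no genes pass the mean-count filter (> %g in %s samples); consider lowering the threshold",
      threshold, if (mode == "no_spikeins") "input" else "eluate/supernatant"),
      call. = FALSE)
  }
  out
}

#' Write per-gene results
#'
#' Emits a tab-separated table with columns `gene_id`, `mu_hat`,
#' `gamma_hat`, `alpha_hat`, `alpha_lower`, `alpha_upper`, `converged`,
#' `flags`. Confidence columns are `NA` when no interval table is supplied.
#'
#' @param fit a `modlevel_fit` object from [fit_modlevel()].
#' @param ci optional interval table from [ci_all()].
#' @param path output path.
#' @export
write_results <- function(fit, ci = NULL, path) {
  est <- fit$estimates
  out <- data.frame(gene_id = est$gene_id,
                    mu_hat = est$mu_hat,
                    gamma_hat = est$gamma_hat,
                    alpha_hat = est$alpha_hat,
                    alpha_lower = NA_real_,
                    alpha_upper = NA_real_,
                    converged = est$converged,
                    flags = est$flag,
                    stringsAsFactors = FALSE)
  if (!is.null(ci)) {
    i <- match(out$gene_id, ci$gene_id)
    out$alpha_lower <- ci$alpha_lower[i]
    out$alpha_upper <- ci$alpha_upper[i]
    extra <- ifelse(is.na(i) | !nzchar(ci$flags[i]), "", ci$flags[i])
    out$flags <- ifelse(nzchar(out$flags) & nzchar(extra),
                        paste(out$flags, extra, sep = ";"),
                        paste0(out$flags, extra))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# flat key = value configuration files (comments with '#')
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) {
      stop(sprintf("malformed config line (expected key = value): '%s'", ln),
           call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
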