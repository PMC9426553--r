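#' Construct a replicated expression dataset
#'
#' Bundles a gene x sample TPM matrix with its sample sheet and validates the
#' pair. The sample sheet assigns every column of the matrix a biological
#' condition (e.g., a strain x medium combination such as `"MT_8IL"`), a
#' time point (`"early"` or `"mid"` exponential phase), and a replicate index.
#'
#' @param tpm Numeric matrix of non-negative TPM values, genes as rows
#'   (rownames are gene IDs), samples as columns (colnames are sample IDs).
#' @param samples Data frame with columns `sample_id`, `condition`,
#'   `timepoint`, `replicate`, one row per matrix column.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `tpm`, `samples`, and `gene_ids`.
#' @examples
#' tpm <- matrix(c(10, 20, 5, 12, 22, 6), nrow = 3,
#'               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' sheet <- data.frame(sample_id = c("s1", "s2"), condition = "WT_0IL",
#'                     timepoint = "early", replicate = 1:2)
#' ds <- expression_dataset(tpm, sheet)
#' @export
expression_dataset <- function(tpm, samples) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop("tpm must be a numeric matrix")
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "condition", "timepoint", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$condition <- as.character(samples$condition)
  samples$timepoint <- as.character(samples$timepoint)
  samples$replicate <- as.integer(samples$replicate)

  if (is.null(rownames(tpm))) stop("tpm matrix must have gene IDs as rownames")
  if (is.null(colnames(tpm))) stop("tpm matrix must have sample IDs as colnames")
  if (anyDuplicated(rownames(tpm))) {
    stop("duplicate gene IDs: ",
         paste(unique(rownames(tpm)[duplicated(rownames(tpm))]), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample IDs in sample sheet")
  if (anyNA(tpm)) stop("missing TPM values are not allowed")
  if (any(tpm < 0)) stop("negative TPM values are not allowed")
  if (!all(samples$timepoint %in% c("early", "mid"))) {
    stop("timepoint must be 'early' or 'mid'")
  }
  if (anyNA(samples$replicate) || any(samples$replicate < 1)) {
    stop("replicate indices must be positive integers")
  }

  extra_sheet <- setdiff(samples$sample_id, colnames(tpm))
  extra_mat <- setdiff(colnames(tpm), samples$sample_id)
  if (length(extra_sheet) > 0) {
    stop("unmatched sample(s) in sheet but not matrix: ",
         paste(extra_sheet, collapse = ", "))
  }
  if (length(extra_mat) > 0) {
    stop("unmatched sample(s) in matrix but not sheet: ",
         paste(extra_mat, collapse = ", "))
  }
  # replicate uniqueness within each condition/timepoint group
  grp <- paste(samples$condition, samples$timepoint, sep = "\r")
  if (any(tapply(samples$replicate, grp, anyDuplicated) > 0)) {
    stop("replicate indices must be unique within each condition/timepoint group")
  }

  # align sheet rows to matrix column order
  samples <- samples[match(colnames(tpm), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(tpm = tpm, samples = samples, gene_ids = rownames(tpm)),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", length(x$gene_ids), "genes x",
      nrow(x$samples), "samples\n")
  tab <- table(x$samples$condition, x$samples$timepoint)
  cat("replicates per condition/timepoint:\n")
  print(tab)
  invisible(x)
}

#' Load an expression matrix and sample sheet from delimited text
#'
#' The matrix file has a gene-ID first column and one numeric column per
#' sample, with sample IDs in the header. The sample sheet has columns
#' `sample_id`, `condition`, `timepoint`, `replicate`. The delimiter (tab or
#' comma) is auto-detected from the header line unless given explicitly.
#'
#' @param matrix_path Path to the TPM matrix file.
#' @param sample_sheet_path Path to the sample sheet file.
#' @param sep Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   per file.
#' @return An [expression_dataset()].
#' @export
load_expression <- function(matrix_path, sample_sheet_path, sep = NULL) {
  mat_df <- read_delim_auto(matrix_path, sep)
  if (ncol(mat_df) < 2) stop("expression matrix needs a gene column and >= 1 sample column")
  gene_ids <- as.character(mat_df[[1]])
  vals <- mat_df[, -1, drop = FALSE]
  non_numeric <- !vapply(vals, is.numeric, logical(1))
  if (any(non_numeric)) {
    stop("non-numeric TPM column(s): ", paste(names(vals)[non_numeric], collapse = ", "))
  }
  tpm <- as.matrix(vals)
  rownames(tpm) <- gene_ids
  sheet <- read_delim_auto(sample_sheet_path, sep)
  expression_dataset(tpm, sheet)
}

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

#' Floor TPM values and convert to log2 scale
#'
#' Every TPM value below `floor` is raised to `floor` before taking log2, so
#' absent and barely-detected transcripts share a common baseline of
#' `log2(floor)` and cannot generate spurious fold changes.
#'
#' @param x An `ExpressionDataset` or a non-negative numeric matrix/vector of
#'   TPM values.
#' @param floor Positive flooring constant (default 5 TPM).
#' @return Numeric matrix (or vector) of `log2(pmax(x, floor))`.
#' @examples
#' floor_and_log2(c(2, 5, 1024))  # log2(5), log2(5), 10
#' @export
floor_and_log2 <- function(x, floor = 5) {
  if (!is.numeric(floor) || length(floor) != 1 || floor <= 0) {
    stop("floor must be a single positive number")
  }
  if (inherits(x, "ExpressionDataset")) x <- x$tpm
  log2(pmax(x, floor))
}

#' Per-gene replicate summary for one condition at one time point
#'
#' Computes, for every gene, the mean and variance over replicates of
#' log2-scale floored TPM, the ingredients of the fold-change scores
#' computed by [score_genes()].
#'
#' @param dataset An [expression_dataset()].
#' @param condition Condition label present in the sample sheet.
#' @param timepoint `"early"` or `"mid"`.
#' @param floor Flooring constant passed to [floor_and_log2()].
#' @param var_denom Variance denominator: `"n-1"` (sample variance, default)
#'   or `"n"` (population variance).
#' @param average_before_log2 If `TRUE`, the per-gene mean is
#'   `log2(mean(floored TPM))` instead of the default mean of per-replicate
#'   log2 values; the variance is always computed on the per-replicate log2
#'   values, where the downstream scores need it.
#' @return Data frame with columns `gene`, `mean_log2`, `var_log2`, `n`, and
#'   attributes `condition` and `timepoint`.
#' @export
summarize_condition <- function(dataset, condition, timepoint, floor = 5,
                                var_denom = c("n-1", "n"),
                                average_before_log2 = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  var_denom <- match.arg(var_denom)
  sel <- dataset$samples$condition == condition &
    dataset$samples$timepoint == timepoint
  n <- sum(sel)
  if (n == 0) {
    stop("no samples for condition '", condition, "' at timepoint '",
         timepoint, "'")
  }
  if (n < 2) {
    stop("condition '", condition, "' at timepoint '", timepoint,
         "' has ", n, " replicate; >= 2 are required to estimate variance")
  }
  floored <- pmax(dataset$tpm[, sel, drop = FALSE], floor)
  vals <- log2(floored)
  m <- rowMeans(vals)
  denom <- if (var_denom == "n-1") n - 1 else n
  v <- rowSums((vals - m)^2) / denom
  if (average_before_log2) m <- log2(rowMeans(floored))
  out <- data.frame(gene = dataset$gene_ids, mean_log2 = unname(m),
                    var_log2 = unname(v), n = n,
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- condition
  attr(out, "timepoint") <- timepoint
  out
}

#' Long-format replicate summaries for every condition/timepoint group
#'
#' Convenience wrapper around [summarize_condition()] for export.
#'
#' @inheritParams summarize_condition
#' @return Data frame with columns `gene`, `condition`, `timepoint`,
#'   `mean_log2`, `var_log2`, `n`.
#' @export
summarize_all <- function(dataset, floor = 5, var_denom = c("n-1", "n"),
                          average_before_log2 = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  var_denom <- match.arg(var_denom)
  groups <- unique(dataset$samples[, c("condition", "timepoint")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    s <- summarize_condition(dataset, groups$condition[i], groups$timepoint[i],
                             floor = floor, var_denom = var_denom,
                             average_before_log2 = average_before_log2)
    cbind(gene = s$gene, groups[rep(i, nrow(s)), ], s[, c("mean_log2", "var_log2", "n")])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
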