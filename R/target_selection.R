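#' Percentile threshold of a metric
#'
#' @param values Non-empty numeric vector.
#' @param p Percentile in (0, 100), default 75.
#' @param method `"linear_interpolation"` (default; interpolates between
#'   closest order statistics, `stats::quantile` type 7) or `"nearest_rank"`
#'   (inverse-CDF order statistic, type 1).
#' @return The percentile value.
#' @examples
#' percentile_threshold(c(1, 2, 3, 4), 75)  # 3.25
#' @export
percentile_threshold <- function(values, p = 75,
                                 method = c("linear_interpolation",
                                            "nearest_rank")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("values must be non-empty")
  if (!(p > 0 && p < 100)) stop("p must be in (0, 100)")
  type <- if (method == "linear_interpolation") 7L else 1L
  unname(stats::quantile(values, probs = p / 100, type = type, names = FALSE))
}

#' Partition candidate genes into percentile quadrants
#'
#' Computes the p-th percentile of degree (`d*`) and of average fold change
#' (`f*`) over the candidate genes and assigns each gene a quadrant:
#' `Q1_both` (degree >= d* and avg_fc >= f*), `Q2_degree_only`,
#' `Q4_fc_only`, `Q3_neither`. Reaching the percentile is inclusive, so
#' genes tied at the threshold count as inside it.
#'
#' @param targets Data frame with columns `gene`, `degree`, `avg_fc`.
#' @param percentile Percentile for both thresholds (default 75).
#' @param method Percentile method, see [percentile_threshold()].
#' @return `targets` with an added factor column `quadrant`, and attributes
#'   `degree_threshold` and `fc_threshold`.
#' @export
assign_quadrants <- function(targets, percentile = 75,
                             method = c("linear_interpolation",
                                        "nearest_rank")) {
  method <- match.arg(method)
  required <- c("gene", "degree", "avg_fc")
  if (!all(required %in% names(targets))) {
    stop("targets must have columns gene, degree, avg_fc")
  }
  if (nrow(targets) == 0) stop("targets must be non-empty")
  if (anyNA(targets$degree) || anyNA(targets$avg_fc)) {
    stop("every gene needs both a degree and an avg_fc")
  }
  d_star <- percentile_threshold(targets$degree, percentile, method)
  f_star <- percentile_threshold(targets$avg_fc, percentile, method)
  hi_d <- targets$degree >= d_star
  hi_f <- targets$avg_fc >= f_star
  q <- ifelse(hi_d & hi_f, "Q1_both",
              ifelse(hi_d, "Q2_degree_only",
                     ifelse(hi_f, "Q4_fc_only", "Q3_neither")))
  targets$quadrant <- factor(q, levels = c("Q1_both", "Q2_degree_only",
                                           "Q3_neither", "Q4_fc_only"))
  attr(targets, "degree_threshold") <- d_star
  attr(targets, "fc_threshold") <- f_star
  targets
}

# deterministic total order: primary metric descending, secondary metric
# descending, then gene ID ascending
rank_genes <- function(df, primary, secondary) {
  df[order(-df[[primary]], -df[[secondary]], df$gene), , drop = FALSE]
}

#' Select top-k target groups from the quadrant table
#'
#' Four groups are drawn: `by_degree` (top k of quadrant Q2 ranked by
#' degree), `overlap_by_degree` (top k of Q1 by degree),
#' `overlap_by_fold_change` (top k of Q1 by average fold change — a gene can
#' appear in both overlap groups), and `by_fold_change` (top k of Q4 by
#' average fold change). Ties at the boundary break by the other metric,
#' then by gene ID, so selection is deterministic and independent of input
#' row order. A quadrant with fewer than k members yields all of them with a
#' warning.
#'
#' @param table Output of [assign_quadrants()].
#' @param k Number of genes per group (default 5).
#' @return A list with elements `groups` (named list of ranked data frames,
#'   each with a `rank` column), `table` (input table with a
#'   comma-separated `groups` column added), and `thresholds`.
#' @export
select_targets <- function(table, k = 5) {
  if (is.null(table$quadrant)) stop("assign_quadrants() must be run first")
  if (!(is.numeric(k) && length(k) == 1 && k >= 1)) stop("k must be a positive integer")
  k <- as.integer(k)

  spec <- list(
    by_degree = list(quadrant = "Q2_degree_only", primary = "degree", secondary = "avg_fc"),
    overlap_by_degree = list(quadrant = "Q1_both", primary = "degree", secondary = "avg_fc"),
    overlap_by_fold_change = list(quadrant = "Q1_both", primary = "avg_fc", secondary = "degree"),
    by_fold_change = list(quadrant = "Q4_fc_only", primary = "avg_fc", secondary = "degree")
  )
  groups <- lapply(names(spec), function(gname) {
    s <- spec[[gname]]
    pool <- table[table$quadrant == s$quadrant, , drop = FALSE]
    ranked <- rank_genes(pool, s$primary, s$secondary)
    if (nrow(ranked) < k) {
      warning("group '", gname, "': quadrant ", s$quadrant, " has only ",
              nrow(ranked), " gene(s), fewer than k = ", k)
    }
    top <- utils::head(ranked, k)
    if (nrow(top) > 0) top$rank <- seq_len(nrow(top))
    else top$rank <- integer(0)
    rownames(top) <- NULL
    top
  })
  names(groups) <- names(spec)

  membership <- vapply(table$gene, function(g) {
    inn <- names(groups)[vapply(groups, function(df) g %in% df$gene, logical(1))]
    paste(inn, collapse = ",")
  }, character(1))
  table$groups <- unname(membership)

  list(groups = groups, table = table,
       thresholds = c(degree = attr(table, "degree_threshold"),
                      avg_fc = attr(table, "fc_threshold")))
}
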