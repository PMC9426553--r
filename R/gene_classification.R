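#' The six gene classes
#'
#' Every gene in a pairwise comparison of two biological conditions (BC1 vs
#' BC2) falls in exactly one class: upregulated by one side at both time
#' points, increasing on one side (flat early, up at mid, with a regulation
#' shift), changed regulation (a time-profile change that is neither), or no
#' change.
#'
#' @return Character vector of the six class labels, in rule-evaluation order.
#' @export
gene_classes <- function() {
  c("BC1_UPREGULATED", "BC1_INCREASING", "BC2_UPREGULATED",
    "BC2_INCREASING", "CHANGED_REGULATION", "NO_CHANGE")
}

#' Variance-moderated fold-change scores for a pairwise comparison
#'
#' For each gene, three scores compare condition BC1 against BC2 on the log2
#' scale:
#' \describe{
#'   \item{X}{early-exponential fold change:
#'     \eqn{(m_{1e} - m_{2e}) / \sqrt{c + V_{1e}/N_{1e} + V_{2e}/N_{2e}}}}
#'   \item{Y}{mid-exponential fold change, same form with mid-phase terms}
#'   \item{Z}{regulation score, the difference of within-condition time
#'     trajectories \eqn{(m_{1m}-m_{1e}) - (m_{2m}-m_{2e})} over the root of
#'     the pseudovariance plus all four \eqn{V/N} terms}
#' }
#' where \eqn{m}, \eqn{V}, \eqn{N} are the per-gene replicate mean, variance
#' and count of log2 floored TPM, and \eqn{c} is the pseudovariance constant
#' that keeps low-variance genes from inflating the scores. `avg_fc` is
#' `(X + Y) / 2`.
#'
#' @param sum_bc1_early,sum_bc1_mid,sum_bc2_early,sum_bc2_mid Replicate
#'   summaries from [summarize_condition()], all over the same genes in the
#'   same order.
#' @param pseudovariance Positive constant added inside the denominators
#'   (default 0.25).
#' @param sqrt_denominator If `TRUE` (default) the denominator is the square
#'   root of (pseudovariance + variance terms); `FALSE` uses the un-rooted
#'   sum, for sensitivity checks.
#' @return Data frame with columns `gene`, `x`, `y`, `z`, `avg_fc`.
#' @export
score_genes <- function(sum_bc1_early, sum_bc1_mid, sum_bc2_early,
                        sum_bc2_mid, pseudovariance = 0.25,
                        sqrt_denominator = TRUE) {
  if (!is.numeric(pseudovariance) || length(pseudovariance) != 1 ||
      pseudovariance <= 0) {
    stop("pseudovariance must be a single positive number")
  }
  sums <- list(sum_bc1_early, sum_bc1_mid, sum_bc2_early, sum_bc2_mid)
  genes <- sum_bc1_early$gene
  ok <- vapply(sums, function(s) identical(s$gene, genes), logical(1))
  if (!all(ok)) stop("the four summaries must cover identical gene sets in identical order")

  vn <- function(s) s$var_log2 / s$n
  root <- if (sqrt_denominator) sqrt else identity

  den_x <- root(pseudovariance + vn(sum_bc1_early) + vn(sum_bc2_early))
  den_y <- root(pseudovariance + vn(sum_bc1_mid) + vn(sum_bc2_mid))
  den_z <- root(pseudovariance + vn(sum_bc1_mid) + vn(sum_bc1_early) +
                  vn(sum_bc2_mid) + vn(sum_bc2_early))

  x <- (sum_bc1_early$mean_log2 - sum_bc2_early$mean_log2) / den_x
  y <- (sum_bc1_mid$mean_log2 - sum_bc2_mid$mean_log2) / den_y
  z <- ((sum_bc1_mid$mean_log2 - sum_bc1_early$mean_log2) -
          (sum_bc2_mid$mean_log2 - sum_bc2_early$mean_log2)) / den_z

  data.frame(gene = genes, x = x, y = y, z = z, avg_fc = (x + y) / 2,
             stringsAsFactors = FALSE)
}

#' Assign each score triple to one of the six gene classes
#'
#' Rules are evaluated in order with threshold `t = fc_thresh` on X and Y and
#' `r = reg_thresh` on Z; the first matching rule wins:
#' BC1 upregulated (X >= t and Y >= t); BC1 increasing (-t < X < t, Y >= t,
#' Z >= r); BC2 upregulated (X <= -t and Y <= -t); BC2 increasing
#' (-t < X < t, Y <= -t, Z <= -r); changed regulation (|Z| >= r); otherwise
#' no change. A gene matching an upregulated or increasing rule is never
#' relabelled changed-regulation, whatever its Z.
#'
#' @param x,y,z Numeric vectors of equal length (finite).
#' @param fc_thresh Fold-change threshold `t` applied to X and Y (default 1).
#' @param reg_thresh Regulation threshold `r` applied to Z (default 1.5).
#' @return Factor with levels [gene_classes()].
#' @examples
#' classify_scores(1.5, 2.0, 0)      # BC1_UPREGULATED
#' classify_scores(0.2, 1.3, 1.7)    # BC1_INCREASING
#' classify_scores(1.2, -1.2, -2.0)  # CHANGED_REGULATION
#' @export
classify_scores <- function(x, y, z, fc_thresh = 1, reg_thresh = 1.5) {
  if (!(fc_thresh > 0) || !(reg_thresh > 0)) {
    stop("fc_thresh and reg_thresh must be positive")
  }
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z must have equal lengths")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop("scores must be finite")
  }
  t <- fc_thresh
  r <- reg_thresh
  cls <- rep("NO_CHANGE", n)
  # assign in reverse priority so that earlier (higher-priority) rules
  # overwrite later ones; the four directional rules are pairwise disjoint
  cls[abs(z) >= r] <- "CHANGED_REGULATION"
  cls[x > -t & x < t & y <= -t & z <= -r] <- "BC2_INCREASING"
  cls[x <= -t & y <= -t] <- "BC2_UPREGULATED"
  cls[x > -t & x < t & y >= t & z >= r] <- "BC1_INCREASING"
  cls[x >= t & y >= t] <- "BC1_UPREGULATED"
  factor(cls, levels = gene_classes())
}

#' Score and classify every gene for one pairwise comparison
#'
#' @param dataset An [expression_dataset()] containing both conditions at
#'   both time points.
#' @param bc1,bc2 Condition labels: `bc1` is the numerator (first) condition.
#' @param floor Flooring constant for [floor_and_log2()].
#' @param pseudovariance,sqrt_denominator Passed to [score_genes()].
#' @param fc_thresh,reg_thresh Passed to [classify_scores()].
#' @param var_denom,average_before_log2 Passed to [summarize_condition()].
#' @return Data frame with one row per gene (input order): `gene`, `x`, `y`,
#'   `z`, `avg_fc`, `class`.
#' @export
classify_comparison <- function(dataset, bc1, bc2, floor = 5,
                                pseudovariance = 0.25, fc_thresh = 1,
                                reg_thresh = 1.5,
                                var_denom = c("n-1", "n"),
                                sqrt_denominator = TRUE,
                                average_before_log2 = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (identical(bc1, bc2)) stop("bc1 and bc2 must differ")
  var_denom <- match.arg(var_denom)
  sums <- lapply(list(c(bc1, "early"), c(bc1, "mid"),
                      c(bc2, "early"), c(bc2, "mid")),
                 function(ct) summarize_condition(dataset, ct[1], ct[2],
                                                  floor = floor,
                                                  var_denom = var_denom,
                                                  average_before_log2 = average_before_log2))
  scores <- score_genes(sums[[1]], sums[[2]], sums[[3]], sums[[4]],
                        pseudovariance = pseudovariance,
                        sqrt_denominator = sqrt_denominator)
  scores$class <- classify_scores(scores$x, scores$y, scores$z,
                                  fc_thresh = fc_thresh,
                                  reg_thresh = reg_thresh)
  scores
}

#' Tally genes per class
#'
#' @param classification Output of [classify_comparison()].
#' @return Data frame with columns `class` and `count`, one row per class
#'   (all six classes present, zero-filled).
#' @export
class_counts <- function(classification) {
  tab <- table(factor(classification$class, levels = gene_classes()))
  data.frame(class = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
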