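write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_msg <- function(verbose, ...) if (verbose) message("[gecco] ", ...)

#' Run the full gene coexpression connectivity pipeline
#'
#' Executes the end-to-end analysis for one pairwise comparison:
#' \enumerate{
#'   \item classify every gene (bc1 vs bc2) by its X/Y/Z scores;
#'   \item build the Pearson coexpression network over the classified
#'     (non-NO_CHANGE) genes, using the replicate samples of the network
#'     conditions at both time points;
#'   \item reduce the network to the genes upregulated by bc1;
#'   \item compute degree centrality on the reduced subnetwork;
#'   \item partition those genes into percentile quadrants of degree vs
#'     average fold change and select the top-k target groups.
#' }
#' Identical inputs and configuration produce identical outputs.
#'
#' @param dataset An [expression_dataset()].
#' @param bc1,bc2 The comparison conditions; candidate targets are genes
#'   upregulated by `bc1`.
#' @param network_conditions Conditions whose samples feed the correlation
#'   (default `c(bc1, bc2)`, i.e., 2 conditions x 2 time points x replicates).
#' @param out_dir If non-NULL, write all result tables plus a JSON run
#'   manifest there.
#' @param floor,pseudovariance,fc_thresh,reg_thresh,var_denom,sqrt_denominator,average_before_log2
#'   Classification parameters, see [classify_comparison()].
#' @param r_cutoff,absolute,network_log2 Network parameters, see
#'   [build_network()].
#' @param percentile,percentile_method,k Selection parameters, see
#'   [assign_quadrants()] and [select_targets()].
#' @param graphml If `TRUE` and `out_dir` is set, also export the full and
#'   reduced networks as GraphML.
#' @param verbose Emit per-stage progress messages (to stderr).
#' @return List with `classification`, `counts`, `network`, `subnetwork`,
#'   `degrees`, `targets` (see [select_targets()]), and `manifest`.
#' @export
run_gecco <- function(dataset, bc1, bc2, network_conditions = c(bc1, bc2),
                      out_dir = NULL, floor = 5, pseudovariance = 0.25,
                      fc_thresh = 1, reg_thresh = 1.5, r_cutoff = 0.95,
                      absolute = FALSE, network_log2 = FALSE,
                      percentile = 75,
                      percentile_method = c("linear_interpolation",
                                            "nearest_rank"),
                      k = 5, var_denom = c("n-1", "n"),
                      sqrt_denominator = TRUE, average_before_log2 = FALSE,
                      graphml = FALSE, verbose = TRUE) {
  percentile_method <- match.arg(percentile_method)
  var_denom <- match.arg(var_denom)

  stage_msg(verbose, "classify: ", bc1, " vs ", bc2)
  classification <- classify_comparison(dataset, bc1, bc2, floor = floor,
                                        pseudovariance = pseudovariance,
                                        fc_thresh = fc_thresh,
                                        reg_thresh = reg_thresh,
                                        var_denom = var_denom,
                                        sqrt_denominator = sqrt_denominator,
                                        average_before_log2 = average_before_log2)
  counts <- class_counts(classification)
  stage_msg(verbose, "class counts: ",
            paste(counts$class, counts$count, sep = "=", collapse = ", "))

  classified <- classification$gene[classification$class != "NO_CHANGE"]
  if (length(classified) == 0) stop("network stage: no classified (non-NO_CHANGE) genes")
  stage_msg(verbose, "network: ", length(classified), " classified genes, r >= ",
            r_cutoff)
  network <- build_network(dataset, conditions = network_conditions,
                           genes = classified, r_cutoff = r_cutoff,
                           absolute = absolute, use_log2 = network_log2,
                           floor = floor)
  stage_msg(verbose, "network: ", igraph::ecount(network), " edges")

  up_genes <- classification$gene[classification$class == "BC1_UPREGULATED"]
  stage_msg(verbose, "reduce: ", length(up_genes), " upregulated genes")
  subnetwork <- reduce_subnetwork(network, up_genes)
  degrees <- degree_centrality(subnetwork)

  cand <- merge(degrees,
                classification[, c("gene", "avg_fc")], by = "gene", sort = TRUE)
  targets <- NULL
  if (nrow(cand) > 0) {
    cand <- assign_quadrants(cand, percentile = percentile,
                             method = percentile_method)
    targets <- select_targets(cand, k = k)
    stage_msg(verbose, "select: thresholds degree >= ",
              signif(targets$thresholds["degree"], 6), ", avg_fc >= ",
              signif(targets$thresholds["avg_fc"], 6))
  } else {
    warning("selection stage: empty upregulated subnetwork, no targets")
  }

  manifest <- list(
    config = list(bc1 = bc1, bc2 = bc2,
                  network_conditions = network_conditions, floor = floor,
                  pseudovariance = pseudovariance, fc_thresh = fc_thresh,
                  reg_thresh = reg_thresh, r_cutoff = r_cutoff,
                  absolute = absolute, network_log2 = network_log2,
                  percentile = percentile,
                  percentile_method = percentile_method, k = k,
                  var_denom = var_denom, sqrt_denominator = sqrt_denominator,
                  average_before_log2 = average_before_log2),
    n_genes = length(dataset$gene_ids),
    n_samples = nrow(dataset$samples),
    class_counts = stats::setNames(as.list(counts$count), counts$class),
    n_classified = length(classified),
    network_edges = igraph::ecount(network),
    subnetwork_nodes = igraph::vcount(subnetwork),
    subnetwork_edges = igraph::ecount(subnetwork),
    thresholds = if (!is.null(targets)) as.list(targets$thresholds) else NULL,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  result <- list(classification = classification, counts = counts,
                 network = network, subnetwork = subnetwork,
                 degrees = degrees, targets = targets, manifest = manifest)
  if (!is.null(out_dir)) write_gecco_outputs(result, out_dir, graphml = graphml)
  result
}

write_gecco_outputs <- function(result, out_dir, graphml = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cls <- result$classification
  cls$class <- as.character(cls$class)
  write_tsv(cls, file.path(out_dir, "classification.tsv"))
  write_tsv(result$counts, file.path(out_dir, "class_counts.tsv"))
  write_tsv(edge_list(result$network), file.path(out_dir, "edges.tsv"))
  write_tsv(edge_list(result$subnetwork),
            file.path(out_dir, "subnetwork_edges.tsv"))
  write_tsv(result$degrees, file.path(out_dir, "degree.tsv"))
  if (!is.null(result$targets)) {
    tab <- result$targets$table
    tab$quadrant <- as.character(tab$quadrant)
    write_tsv(tab, file.path(out_dir, "targets.tsv"))
    groups <- lapply(result$targets$groups, function(df) {
      df$quadrant <- as.character(df$quadrant)
      df[, c("gene", "degree", "avg_fc", "quadrant", "rank")]
    })
    jsonlite::write_json(
      list(thresholds = as.list(result$targets$thresholds), groups = groups),
      file.path(out_dir, "targets_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (graphml) {
    igraph::write_graph(result$network,
                        file.path(out_dir, "network.graphml"), format = "graphml")
    igraph::write_graph(result$subnetwork,
                        file.path(out_dir, "subnetwork.graphml"), format = "graphml")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' The four canonical pairwise comparisons of a two-strain stress design
#'
#' For condition labels of the form `<strain>_<medium>` with strains WT/MT
#' and media 0IL/8IL: (i) strain effect without stressor, (ii) stressor
#' effect in WT, (iii) stressor effect in MT, (iv) strain effect under
#' stressor.
#'
#' @return Named list of `c(bc1, bc2)` pairs.
#' @export
default_comparisons <- function() {
  list(MT0_vs_WT0 = c("MT_0IL", "WT_0IL"),
       WT8_vs_WT0 = c("WT_8IL", "WT_0IL"),
       MT8_vs_MT0 = c("MT_8IL", "MT_0IL"),
       MT8_vs_WT8 = c("MT_8IL", "WT_8IL"))
}

#' Classify every gene for a set of pairwise comparisons
#'
#' @param dataset An [expression_dataset()] containing every condition used.
#' @param comparisons Named list of `c(bc1, bc2)` label pairs (default
#'   [default_comparisons()]).
#' @param out_dir If non-NULL, write one classification TSV and one count
#'   TSV per comparison.
#' @param ... Classification parameters passed to [classify_comparison()].
#' @return Named list with one element per comparison, each a list of
#'   `classification` and `counts`.
#' @export
run_all_comparisons <- function(dataset, comparisons = default_comparisons(),
                                out_dir = NULL, ...) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  have <- unique(dataset$samples$condition)
  needed <- unique(unlist(comparisons))
  missing_cond <- setdiff(needed, have)
  if (length(missing_cond) > 0) {
    stop("dataset is missing condition(s): ", paste(missing_cond, collapse = ", "))
  }
  out <- lapply(names(comparisons), function(nm) {
    pair <- comparisons[[nm]]
    classification <- classify_comparison(dataset, pair[1], pair[2], ...)
    counts <- class_counts(classification)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      cls <- classification
      cls$class <- as.character(cls$class)
      write_tsv(cls, file.path(out_dir, paste0("classification_", nm, ".tsv")))
      write_tsv(counts, file.path(out_dir, paste0("class_counts_", nm, ".tsv")))
    }
    list(classification = classification, counts = counts)
  })
  names(out) <- names(comparisons)
  out
}
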