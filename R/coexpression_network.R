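#' Pearson correlation of two expression profiles
#'
#' Standard product-moment correlation, with the degenerate case made
#' explicit: a profile with zero variance (e.g., a gene floored to a constant
#' in every sample) has no defined correlation and returns `NA`, which
#' [build_network()] treats as "not connected".
#'
#' @param u,v Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA_real_` if either vector is
#'   constant.
#' @export
pearson_r <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must have equal lengths")
  if (length(u) < 3) stop("need at least 3 paired samples")
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(NA_real_)
  stats::cor(u, v)
}

#' Build a thresholded Pearson coexpression network
#'
#' Computes all pairwise Pearson correlations between gene expression
#' profiles over a chosen set of samples and connects two genes whenever the
#' correlation passes a stringent cutoff (default r >= 0.95, signed). By
#' default correlation is computed on the raw TPM values of the individual
#' replicate samples.
#'
#' @param dataset An [expression_dataset()].
#' @param conditions Condition labels whose samples enter the correlation;
#'   `NULL` uses every condition.
#' @param timepoints Time points to include (default both).
#' @param genes Gene IDs to use as nodes; `NULL` uses all genes. Unknown IDs
#'   are an error.
#' @param r_cutoff Correlation cutoff (default 0.95).
#' @param absolute If `TRUE`, threshold `|r|` instead of signed `r`, so that
#'   strong anticorrelation also connects.
#' @param use_log2 If `TRUE`, correlate log2 floored values rather than raw
#'   TPM.
#' @param floor Flooring constant used when `use_log2 = TRUE`.
#' @return An undirected `igraph` graph whose vertices are the requested
#'   genes and whose edges carry the correlation as the `weight` attribute;
#'   graph attributes record `r_cutoff` and `absolute`. Genes with constant
#'   profiles are isolated vertices.
#' @export
build_network <- function(dataset, conditions = NULL,
                          timepoints = c("early", "mid"), genes = NULL,
                          r_cutoff = 0.95, absolute = FALSE,
                          use_log2 = FALSE, floor = 5) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  sel <- dataset$samples$timepoint %in% timepoints
  if (!is.null(conditions)) {
    unknown <- setdiff(conditions, unique(dataset$samples$condition))
    if (length(unknown) > 0) {
      stop("unknown condition(s): ", paste(unknown, collapse = ", "))
    }
    sel <- sel & dataset$samples$condition %in% conditions
  }
  if (sum(sel) < 3) stop("need at least 3 samples after filtering, got ", sum(sel))
  if (is.null(genes)) genes <- dataset$gene_ids
  if (length(genes) == 0) stop("gene set must be non-empty")
  unknown_genes <- setdiff(genes, dataset$gene_ids)
  if (length(unknown_genes) > 0) {
    stop("gene(s) not in dataset: ", paste(utils::head(unknown_genes, 5), collapse = ", "))
  }

  m <- dataset$tpm[genes, sel, drop = FALSE]
  if (use_log2) m <- log2(pmax(m, floor))
  cm <- suppressWarnings(stats::cor(t(m)))  # NA rows for constant genes
  score <- if (absolute) abs(cm) else cm
  adj <- !is.na(score) & score >= r_cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    igraph::E(g)$weight <- cm[cbind(el[, 1], el[, 2])]
  } else {
    g <- igraph::set_edge_attr(g, "weight", value = numeric(0))
  }
  g <- igraph::set_graph_attr(g, "r_cutoff", r_cutoff)
  igraph::set_graph_attr(g, "absolute", absolute)
}

#' Reduce a network to the subgraph induced by a gene set
#'
#' Keeps only the named genes and the edges with both endpoints kept; degrees
#' downstream are recomputed on the reduced graph. IDs not present in the
#' network are ignored with a warning, and an empty result is allowed (with a
#' warning).
#'
#' @param network An `igraph` graph from [build_network()].
#' @param keep Character vector of gene IDs to retain.
#' @return The induced subgraph, carrying over graph attributes.
#' @export
reduce_subnetwork <- function(network, keep) {
  nodes <- igraph::V(network)$name
  absent <- setdiff(keep, nodes)
  if (length(absent) > 0) {
    warning(length(absent), " gene(s) in keep set absent from network; ignored")
  }
  kept <- intersect(nodes, keep)
  if (length(kept) == 0) warning("reduced network is empty")
  igraph::induced_subgraph(network, kept)
}

#' Degree centrality of every node
#'
#' Degree is the raw count of edges incident to a gene (not normalized), the
#' connectivity metric used to rank candidate genes.
#'
#' @param network An `igraph` graph.
#' @return Data frame with columns `gene` and `degree`.
#' @export
degree_centrality <- function(network) {
  d <- igraph::degree(network, loops = FALSE)
  data.frame(gene = igraph::V(network)$name, degree = as.integer(d),
             stringsAsFactors = FALSE)
}

#' Edge list of a network as a data frame
#'
#' @param network An `igraph` graph with a `weight` edge attribute.
#' @return Data frame with columns `gene_a`, `gene_b`, `r`.
#' @export
edge_list <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- if (igraph::ecount(network) > 0) igraph::E(network)$weight else numeric(0)
  data.frame(gene_a = as.character(el[, 1]), gene_b = as.character(el[, 2]),
             r = w, stringsAsFactors = FALSE)
}
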