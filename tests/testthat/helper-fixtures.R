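# shared fixture builders; all data is generated in code

# sample sheet for a full conditions x {early, mid} x replicates grid,
# sample IDs in the generator's dialect
grid_sheet <- function(conditions, n_rep = 3) {
  s <- expand.grid(replicate = seq_len(n_rep), timepoint = c("early", "mid"),
                   condition = conditions, stringsAsFactors = FALSE)
  data.frame(sample_id = paste(s$condition, s$timepoint,
                               paste0("r", s$replicate), sep = "_"),
             condition = s$condition, timepoint = s$timepoint,
             replicate = s$replicate, stringsAsFactors = FALSE)
}

# dataset from an explicit TPM matrix over a grid sheet
grid_dataset <- function(tpm, conditions, n_rep = 3) {
  sheet <- grid_sheet(conditions, n_rep)
  colnames(tpm) <- sheet$sample_id
  expression_dataset(tpm, sheet)
}

# a planted-classes table with no rows, for module-only simulations
no_planted_classes <- function() {
  data.frame(class = character(), count = integer(),
             delta_early = numeric(), delta_mid = numeric())
}

# scaled-down planted design for fast tests (same classes and effect sizes
# as the defaults, smaller counts)
small_planted_classes <- function() {
  pc <- default_planted_classes()
  pc$count <- c(10, 10, 10, 10, 5)
  pc
}

small_modules <- function() {
  data.frame(size = c(5, 5), latent_sd = 2, member_noise_sd = 0.2)
}

small_config <- function(n_genes = 100, seed = 1, ...) {
  simulation_config(n_genes = n_genes, seed = seed,
                    planted_classes = small_planted_classes(),
                    modules = small_modules(), ...)
}

no_modules <- function() {
  data.frame(size = integer(), latent_sd = numeric(),
             member_noise_sd = numeric())
}

# independent brute-force network oracle: per-pair loop calling cor() on
# each pair separately (never the matrix path used by build_network)
brute_force_edges <- function(m, cutoff, absolute = FALSE) {
  genes <- rownames(m)
  rows <- list()
  for (i in seq_along(genes)) {
    for (j in seq_len(i - 1)) {
      u <- m[j, ]
      v <- m[i, ]
      if (stats::sd(u) == 0 || stats::sd(v) == 0) next
      r <- stats::cor(u, v)
      s <- if (absolute) abs(r) else r
      if (s >= cutoff) {
        rows[[length(rows) + 1]] <- data.frame(a = genes[j], b = genes[i],
                                               r = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(a = character(), b = character(), r = numeric()))
  }
  do.call(rbind, rows)
}

# canonical unordered edge keys for set comparison
edge_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# scalar reference classifier: literal if/else chain in rule order,
# independent of the vectorized implementation
classify_one_ref <- function(x, y, z, t = 1, r = 1.5) {
  if (x >= t && y >= t) return("BC1_UPREGULATED")
  if (x > -t && x < t && y >= t && z >= r) return("BC1_INCREASING")
  if (x <= -t && y <= -t) return("BC2_UPREGULATED")
  if (x > -t && x < t && y <= -t && z <= -r) return("BC2_INCREASING")
  if (abs(z) >= r) return("CHANGED_REGULATION")
  "NO_CHANGE"
}

# minimal replicate-summary table for direct score_genes() input
summary_table <- function(genes, mean_log2, var_log2, n = 3) {
  data.frame(gene = genes, mean_log2 = mean_log2, var_log2 = var_log2,
             n = n, stringsAsFactors = FALSE)
}
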