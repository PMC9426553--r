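#' Configuration for the synthetic transcriptome generator
#'
#' Describes a replicated multi-condition two-time-point TPM experiment with
#' known ground truth: a set of planted gene classes (log2 effect sizes
#' applied to a designated comparison condition at each time point) and a set
#' of planted coexpression modules (latent profiles shared by module members
#' across all samples). Effects and noise live on the log2 scale and are
#' exponentiated to TPM, which keeps planted scores analytically predictable
#' and guarantees positive values.
#'
#' The defaults mirror the study design the scoring method assumes: 4
#' biological conditions (two strains with and without stressor), 2
#' exponential-phase time points, 3 replicates, and a designated comparison
#' of the second strain against the first under stress.
#'
#' @param n_genes Number of genes (default 1000).
#' @param conditions Condition labels (default
#'   `c("WT_0IL", "WT_8IL", "MT_0IL", "MT_8IL")`).
#' @param bc1,bc2 The designated comparison: planted deltas shift `bc1`
#'   relative to every other condition (default `"MT_8IL"` vs `"WT_8IL"`).
#' @param n_replicates Replicates per condition/timepoint (default 3).
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of per-gene
#'   baseline log2 TPM (defaults 6 and 2: a median of ~64 TPM with a wide
#'   dynamic range).
#' @param noise_sd Replicate noise standard deviation on the log2 scale
#'   (default 0.25, typical bulk RNA-seq replicate variability).
#' @param planted_classes Data frame with columns `class`, `count`,
#'   `delta_early`, `delta_mid`; see [default_planted_classes()].
#' @param modules Data frame with columns `size`, `latent_sd`,
#'   `member_noise_sd`; see [default_modules()]. Modules are planted on
#'   background (unclassed) genes.
#' @param seed Integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000,
                              conditions = c("WT_0IL", "WT_8IL",
                                             "MT_0IL", "MT_8IL"),
                              bc1 = "MT_8IL", bc2 = "WT_8IL",
                              n_replicates = 3,
                              baseline_log2_mean = 6, baseline_log2_sd = 2,
                              noise_sd = 0.25,
                              planted_classes = default_planted_classes(),
                              modules = default_modules(),
                              seed = 1) {
  stopifnot(n_genes >= 1, n_replicates >= 1,
            baseline_log2_sd >= 0, noise_sd >= 0)
  if (!all(c(bc1, bc2) %in% conditions)) stop("bc1 and bc2 must be among conditions")
  if (bc1 == bc2) stop("bc1 and bc2 must differ")
  planted_classes <- as.data.frame(planted_classes, stringsAsFactors = FALSE)
  modules <- as.data.frame(modules, stringsAsFactors = FALSE)
  if (nrow(planted_classes) > 0) {
    stopifnot(all(c("class", "count", "delta_early", "delta_mid") %in%
                    names(planted_classes)))
    bad <- setdiff(planted_classes$class, gene_classes())
    if (length(bad) > 0) stop("unknown planted class(es): ", paste(bad, collapse = ", "))
  }
  if (nrow(modules) > 0) {
    stopifnot(all(c("size", "latent_sd", "member_noise_sd") %in% names(modules)),
              all(modules$latent_sd >= 0), all(modules$member_noise_sd >= 0))
  }
  n_planted <- sum(planted_classes$count)
  n_module <- sum(modules$size)
  if (n_planted + n_module > n_genes) {
    stop("planted class counts plus module sizes exceed n_genes")
  }
  structure(list(n_genes = n_genes, conditions = conditions, bc1 = bc1,
                 bc2 = bc2, n_replicates = n_replicates,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
                 planted_classes = planted_classes, modules = modules,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default planted gene classes
#'
#' Effect sizes of 3 log2 units comfortably clear the class-defining
#' thresholds (a zero-variance delta of 3 at both time points gives
#' X = Y = 3 / sqrt(0.25) = 6): 50 genes upregulated on each side, 50
#' increasing on each side (flat early, delta at mid, which also drives the
#' regulation score), and 25 changed-regulation genes (delta early only, so
#' the trajectory shifts without meeting an upregulated/increasing rule).
#'
#' @return Data frame with columns `class`, `count`, `delta_early`,
#'   `delta_mid`.
#' @export
default_planted_classes <- function() {
  data.frame(
    class = c("BC1_UPREGULATED", "BC1_INCREASING", "BC2_UPREGULATED",
              "BC2_INCREASING", "CHANGED_REGULATION"),
    count = c(50, 50, 50, 50, 25),
    delta_early = c(3, 0, -3, 0, 3),
    delta_mid = c(3, 3, -3, -3, 0),
    stringsAsFactors = FALSE
  )
}

#' Default planted coexpression modules
#'
#' Two modules of 10 genes with latent-to-noise ratio 10
#' (latent sd 2, member noise sd 0.2 on the log2 scale), giving a true
#' within-module correlation of about 0.99 on the log2 scale before
#' replicate noise.
#'
#' @return Data frame with columns `size`, `latent_sd`, `member_noise_sd`.
#' @export
default_modules <- function() {
  data.frame(size = c(10, 10), latent_sd = 2, member_noise_sd = 0.2)
}

#' Simulate a replicated TPM dataset with known truth
#'
#' Per gene and sample, the log2 value is
#' baseline + planted class delta (bc1 columns only, per time point) +
#' module latent profile + module member noise + replicate noise, and
#' TPM = 2^value. Fully reproducible from the seed in the config; the
#' caller's RNG state is left untouched.
#'
#' @param config A [simulation_config()].
#' @return List with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (data frame `gene`, `planted_class`, `module_id`; background
#'   genes have class `"background"` and `module_id` `NA`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  width <- max(4, nchar(as.character(config$n_genes)))
  genes <- sprintf(paste0("gene_%0", width, "d"), seq_len(config$n_genes))
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         timepoint = c("early", "mid"),
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("condition", "timepoint", "replicate")]
  samples$sample_id <- paste(samples$condition, samples$timepoint,
                             paste0("r", samples$replicate), sep = "_")
  n_s <- nrow(samples)

  baseline <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  vals <- matrix(baseline, nrow = config$n_genes, ncol = n_s)

  # planted class deltas on the bc1 condition columns
  truth_class <- rep("background", config$n_genes)
  pc <- config$planted_classes
  idx <- 0L
  bc1_early <- samples$condition == config$bc1 & samples$timepoint == "early"
  bc1_mid <- samples$condition == config$bc1 & samples$timepoint == "mid"
  if (nrow(pc) > 0) {
    for (i in seq_len(nrow(pc))) {
      rows <- idx + seq_len(pc$count[i])
      truth_class[rows] <- pc$class[i]
      # planted effects sit on genes expressed clear of the 5-TPM detection
      # floor (on both sides of the comparison), so truth labels are exact
      # in the noiseless limit; floor censoring is still exercised by
      # background genes
      guard <- log2(5) + 0.5 + max(0, -pc$delta_early[i], -pc$delta_mid[i])
      lift <- pmax(0, guard - vals[rows, 1])
      vals[rows, ] <- vals[rows, ] + lift
      vals[rows, bc1_early] <- vals[rows, bc1_early] + pc$delta_early[i]
      vals[rows, bc1_mid] <- vals[rows, bc1_mid] + pc$delta_mid[i]
      idx <- idx + pc$count[i]
    }
  }

  # coexpression modules on background genes: one latent profile per module
  # shared by its members, plus small member-specific noise
  module_id <- rep(NA_integer_, config$n_genes)
  mods <- config$modules
  if (nrow(mods) > 0) {
    for (j in seq_len(nrow(mods))) {
      rows <- idx + seq_len(mods$size[j])
      module_id[rows] <- j
      # modules sit on abundantly expressed genes: latent excursions must
      # stay above the detection floor or censoring erodes the planted
      # correlation
      guard <- log2(5) + 0.5 + 3 * mods$latent_sd[j]
      vals[rows, ] <- vals[rows, ] + pmax(0, guard - vals[rows, 1])
      latent <- stats::rnorm(n_s, 0, mods$latent_sd[j])
      member_noise <- matrix(stats::rnorm(mods$size[j] * n_s, 0,
                                          mods$member_noise_sd[j]),
                             nrow = mods$size[j])
      vals[rows, ] <- vals[rows, ] +
        matrix(latent, nrow = mods$size[j], ncol = n_s, byrow = TRUE) +
        member_noise
      idx <- idx + mods$size[j]
    }
  }

  if (config$noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(config$n_genes * n_s, 0, config$noise_sd),
                          nrow = config$n_genes)
  }

  tpm <- 2^vals
  dimnames(tpm) <- list(genes, samples$sample_id)
  truth <- data.frame(gene = genes, planted_class = truth_class,
                      module_id = module_id, stringsAsFactors = FALSE)
  list(dataset = expression_dataset(tpm, samples), truth = truth)
}

#' Recall of planted classes and module connectivity contrast
#'
#' @param truth Truth table from [simulate_dataset()].
#' @param classification Output of [classify_comparison()] on the simulated
#'   dataset (for the designated bc1 vs bc2 comparison).
#' @param degrees Optional [degree_centrality()] table; if given, mean degree
#'   of module members is contrasted with that of non-module genes present
#'   in the same table.
#' @return List with `class_recall` (data frame `class`, `n_planted`,
#'   `n_recovered`, `recall`) and, when `degrees` is supplied,
#'   `module_degree` (data frame `group`, `n`, `mean_degree`).
#' @export
recovery_report <- function(truth, classification, degrees = NULL) {
  if (!setequal(truth$gene, classification$gene)) {
    stop("truth and classification cover different gene sets")
  }
  cls <- classification$class[match(truth$gene, classification$gene)]
  planted <- truth[truth$planted_class != "background", , drop = FALSE]
  planted_cls <- cls[truth$planted_class != "background"]
  per_class <- lapply(unique(planted$planted_class), function(pc) {
    sel <- planted$planted_class == pc
    data.frame(class = pc, n_planted = sum(sel),
               n_recovered = sum(planted_cls[sel] == pc),
               recall = mean(planted_cls[sel] == pc),
               stringsAsFactors = FALSE)
  })
  out <- list(class_recall = do.call(rbind, per_class))

  if (!is.null(degrees)) {
    is_module <- truth$module_id[match(degrees$gene, truth$gene)]
    member <- !is.na(is_module)
    out$module_degree <- data.frame(
      group = c("module", "background"),
      n = c(sum(member), sum(!member)),
      mean_degree = c(mean(degrees$degree[member]),
                      mean(degrees$degree[!member])),
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Write a simulated dataset to disk in the loader's dialect
#'
#' Writes `matrix.tsv` (gene column + one column per sample), `samples.tsv`,
#' `truth.tsv`, and a YAML echo of the configuration.
#'
#' @param sim Output of [simulate_dataset()].
#' @param config The [simulation_config()] used.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.yaml"))
  mat_df <- data.frame(gene = sim$dataset$gene_ids,
                       signif(sim$dataset$tpm, 6), check.names = FALSE,
                       stringsAsFactors = FALSE)
  write_tsv(mat_df, paths["matrix"])
  write_tsv(sim$dataset$samples, paths["samples"])
  write_tsv(sim$truth, paths["truth"])
  cfg <- unclass(config)
  cfg$planted_classes <- as.list(cfg$planted_classes)
  cfg$modules <- as.list(cfg$modules)
  yaml::write_yaml(cfg, paths["config"])
  invisible(paths)
}
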