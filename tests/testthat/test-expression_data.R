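test_that("delimited matrix and sample sheet load into a validated dataset", {
  mat_path <- withr::local_tempfile(fileext = ".tsv")
  sheet_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2",
               "g1\t10\t12",
               "g2\t0\t3.5",
               "g3\t100\t90"), mat_path)
  writeLines(c("sample_id\tcondition\ttimepoint\treplicate",
               "s1\tWT_0IL\tearly\t1",
               "s2\tWT_0IL\tearly\t2"), sheet_path)
  ds <- load_expression(mat_path, sheet_path)
  expect_s3_class(ds, "ExpressionDataset")
  expect_equal(ds$gene_ids, c("g1", "g2", "g3"))
  expect_equal(dim(ds$tpm), c(3L, 2L))
  expect_equal(ds$samples$sample_id, colnames(ds$tpm))

  # comma dialect is auto-detected
  csv_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,10,12", "g2,0,3.5"), csv_path)
  sheet_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,condition,timepoint,replicate",
               "s1,WT_0IL,early,1", "s2,WT_0IL,early,2"), sheet_csv)
  ds_csv <- load_expression(csv_path, sheet_csv)
  expect_equal(unname(ds_csv$tpm[, "s2"]), c(12, 3.5))
})

test_that("malformed inputs are rejected with informative errors", {
  sheet <- data.frame(sample_id = c("s1", "s2"), condition = "c",
                      timepoint = "early", replicate = 1:2)
  tpm <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))

  neg <- tpm; neg[1, 1] <- -1
  expect_error(expression_dataset(neg, sheet), "negative TPM")

  nas <- tpm; nas[2, 2] <- NA
  expect_error(expression_dataset(nas, sheet), "missing TPM")

  dup <- tpm; rownames(dup) <- c("g1", "g1")
  expect_error(expression_dataset(dup, sheet), "duplicate gene")

  sheet_extra <- rbind(sheet, data.frame(sample_id = "S9", condition = "c",
                                         timepoint = "early", replicate = 3))
  expect_error(expression_dataset(tpm, sheet_extra), "unmatched sample.*S9")

  sheet_short <- sheet[1, , drop = FALSE]
  expect_error(expression_dataset(tpm, sheet_short), "unmatched sample")

  sheet_dup_rep <- sheet; sheet_dup_rep$replicate <- c(1, 1)
  expect_error(expression_dataset(tpm, sheet_dup_rep), "replicate indices")

  mat_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\tabc", "g2\t3\t4"), mat_path)
  sheet_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcondition\ttimepoint\treplicate",
               "s1\tc\tearly\t1", "s2\tc\tearly\t2"), sheet_path)
  expect_error(load_expression(mat_path, sheet_path), "non-numeric")
})

test_that("flooring maps sub-floor TPM to log2(floor) and is idempotent", {
  expect_equal(floor_and_log2(c(2, 5, 1024)), c(log2(5), log2(5), 10))
  expect_error(floor_and_log2(1, floor = 0), "positive")

  set.seed(42)
  x <- matrix(stats::runif(60, 0, 200), 10)
  dimnames(x) <- list(paste0("g", 1:10), paste0("s", 1:6))
  once <- floor_and_log2(x)
  twice <- floor_and_log2(2^once)
  expect_identical(twice, once)
})

test_that("replicate summaries match direct arithmetic and are order-invariant", {
  tpm <- matrix(c(5, 5, 5,  4, 8, 16), nrow = 2, byrow = TRUE,
                dimnames = list(c("flat", "ramp"), NULL))
  tpm <- cbind(tpm, tpm + 1)  # mid-phase columns, values unused below
  ds <- grid_dataset(tpm, "WT_0IL", n_rep = 3)

  s <- summarize_condition(ds, "WT_0IL", "early")
  expect_equal(s$n, c(3, 3))
  expect_equal(s$mean_log2[s$gene == "flat"], log2(5))
  expect_equal(s$var_log2[s$gene == "flat"], 0)

  # hand oracle on the floored log2 replicate values {log2 5, 3, 4}
  v <- c(log2(5), 3, 4)
  m_hand <- (v[1] + v[2] + v[3]) / 3
  var_hand <- ((v[1] - m_hand)^2 + (v[2] - m_hand)^2 + (v[3] - m_hand)^2) / 2
  expect_equal(s$mean_log2[s$gene == "ramp"], m_hand)
  expect_equal(s$var_log2[s$gene == "ramp"], var_hand)

  # population-variance option divides by n instead
  s_n <- summarize_condition(ds, "WT_0IL", "early", var_denom = "n")
  expect_equal(s_n$var_log2[s_n$gene == "ramp"], var_hand * 2 / 3)

  # permutation of replicate columns leaves the summary unchanged
  perm <- ds
  ord <- c(3, 1, 2, 4, 5, 6)
  perm <- expression_dataset(ds$tpm[, ord], ds$samples[ord, ])
  s_perm <- summarize_condition(perm, "WT_0IL", "early")
  expect_equal(s_perm, s, ignore_attr = TRUE)

  # averaging before the log2 transform is a config alternative
  s_avg <- summarize_condition(ds, "WT_0IL", "early",
                               average_before_log2 = TRUE)
  expect_equal(s_avg$mean_log2[s_avg$gene == "ramp"], log2((5 + 8 + 16) / 3))
  expect_equal(s_avg$var_log2, s$var_log2)
})

test_that("summaries require a known group with at least two replicates", {
  tpm <- matrix(c(1, 2, 3, 4), 2,
                dimnames = list(c("g1", "g2"), c("a_early_r1", "a_mid_r1")))
  sheet <- data.frame(sample_id = colnames(tpm), condition = "a",
                      timepoint = c("early", "mid"), replicate = 1L)
  ds <- expression_dataset(tpm, sheet)
  expect_error(summarize_condition(ds, "a", "early"), ">= 2")
  expect_error(summarize_condition(ds, "b", "early"), "no samples")
})

test_that("genes fully below the floor have exactly zero variance", {
  set.seed(11)
  tpm <- matrix(stats::runif(18, 0, 5), nrow = 3,
                dimnames = list(paste0("g", 1:3), NULL))
  ds <- grid_dataset(tpm, "c1", n_rep = 3)
  s <- summarize_condition(ds, "c1", "early", floor = 5)
  expect_true(all(s$var_log2 == 0))
  expect_true(all(s$mean_log2 == log2(5)))
})

test_that("summarize_all emits one long-format row set per group", {
  set.seed(5)
  tpm <- matrix(stats::runif(48, 1, 100), nrow = 4,
                dimnames = list(paste0("g", 1:4), NULL))
  ds <- grid_dataset(tpm, c("c1", "c2"), n_rep = 3)
  long <- summarize_all(ds)
  expect_equal(nrow(long), 4 * 4)  # 4 genes x (2 conditions x 2 timepoints)
  expect_setequal(names(long),
                  c("gene", "condition", "timepoint", "mean_log2",
                    "var_log2", "n"))
  one <- summarize_condition(ds, "c2", "mid")
  sub <- long[long$condition == "c2" & long$timepoint == "mid", ]
  expect_equal(sub$mean_log2, one$mean_log2)
})
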