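test_that("pearson_r matches the direct covariance formula and flags degenerates", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)

  u <- c(1, 2, 3, 4)
  v <- c(2, 1, 4, 3)
  # brute-force oracle: sum of cross-deviations over root sums of squares
  du <- u - mean(u); dv <- v - mean(v)
  r_hand <- sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  expect_equal(pearson_r(u, v), r_hand)

  expect_true(is.na(pearson_r(c(2, 2, 2), c(1, 2, 3))))
  expect_error(pearson_r(1:3, 1:4), "equal lengths")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("identical profiles connect at weight 1 and constant genes stay isolated", {
  prof <- c(1, 5, 2, 8, 3, 9)
  tpm <- rbind(a = prof, b = prof, flat = rep(4, 6))
  ds <- grid_dataset(tpm, "c1", n_rep = 3)
  net <- build_network(ds, r_cutoff = 0.95)
  el <- edge_list(net)
  expect_equal(nrow(el), 1)
  expect_setequal(c(el$gene_a, el$gene_b), c("a", "b"))
  expect_equal(el$r, 1)
  deg <- degree_centrality(net)
  expect_equal(deg$degree[deg$gene == "flat"], 0L)
})

test_that("a latent profile yields a triangle with an independent gene isolated", {
  set.seed(8)
  latent <- stats::rnorm(6, 0, 2)
  tpm <- 2^rbind(m1 = 6 + latent + stats::rnorm(6, 0, 0.05),
                 m2 = 7 + latent + stats::rnorm(6, 0, 0.05),
                 m3 = 5 + latent + stats::rnorm(6, 0, 0.05),
                 solo = 6 + stats::rnorm(6, 0, 2))
  ds <- grid_dataset(tpm, "c1", n_rep = 3)
  net <- build_network(ds, r_cutoff = 0.95, use_log2 = TRUE)
  # brute-force all-pairs oracle on the same generated values
  oracle <- brute_force_edges(log2(pmax(tpm, 5)), 0.95)
  expect_setequal(edge_keys(edge_list(net)$gene_a, edge_list(net)$gene_b),
                  edge_keys(oracle$a, oracle$b))
  expect_equal(sort(edge_keys(edge_list(net)$gene_a, edge_list(net)$gene_b)),
               sort(edge_keys(c("m1", "m1", "m2"), c("m2", "m3", "m3"))))
  expect_equal(degree_centrality(net)$degree[4], 0L)
})

test_that("thresholded networks equal the brute-force oracle on random instances", {
  set.seed(31)
  n_genes <- 50
  # half the genes share one of two latent profiles, the rest are free
  latent <- matrix(stats::rnorm(2 * 12, 0, 1.5), 2)
  vals <- matrix(stats::rnorm(n_genes * 12, 6, 1), n_genes)
  vals[1:15, ] <- vals[1:15, ] * 0.1 + matrix(latent[1, ], 15, 12, byrow = TRUE)
  vals[16:30, ] <- vals[16:30, ] * 0.1 + matrix(latent[2, ], 15, 12, byrow = TRUE)
  tpm <- 2^vals
  rownames(tpm) <- sprintf("g%02d", seq_len(n_genes))
  ds <- grid_dataset(tpm, c("c1", "c2"), n_rep = 3)

  for (cutoff in c(0.6, 0.95)) {
    for (absolute in c(FALSE, TRUE)) {
      net <- build_network(ds, r_cutoff = cutoff, absolute = absolute)
      oracle <- brute_force_edges(tpm, cutoff, absolute = absolute)
      el <- edge_list(net)
      expect_setequal(edge_keys(el$gene_a, el$gene_b),
                      edge_keys(oracle$a, oracle$b))
      # weights agree with the per-pair correlations
      key <- edge_keys(el$gene_a, el$gene_b)
      okey <- edge_keys(oracle$a, oracle$b)
      expect_equal(el$r[match(okey, key)], oracle$r)
      # handshake lemma
      expect_equal(sum(degree_centrality(net)$degree),
                   2 * igraph::ecount(net))
    }
  }

  # raising the cutoff never adds edges
  cuts <- c(0.3, 0.6, 0.8, 0.95, 0.99)
  edge_sets <- lapply(cuts, function(ct) {
    el <- edge_list(build_network(ds, r_cutoff = ct))
    edge_keys(el$gene_a, el$gene_b)
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(edge_sets[[i]] %in% edge_sets[[i - 1]]))
  }
})

test_that("build_network validates samples, genes, and conditions", {
  tpm <- matrix(stats::runif(24, 1, 10), 2,
                dimnames = list(c("g1", "g2"), NULL))
  ds <- grid_dataset(tpm, c("c1", "c2"), n_rep = 3)
  expect_error(build_network(ds, conditions = "nope"), "unknown condition")
  expect_error(build_network(ds, genes = character(0)), "non-empty")
  expect_error(build_network(ds, genes = c("g1", "gX")), "not in dataset")

  two_sample <- expression_dataset(
    matrix(c(1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    data.frame(sample_id = c("s1", "s2"), condition = "c1",
               timepoint = "early", replicate = 1:2))
  expect_error(build_network(two_sample), "at least 3 samples")
})

test_that("subnetwork reduction has induced-subgraph semantics", {
  # path a - b - c
  g <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  igraph::E(g)$weight <- c(0.97, 0.98)

  ends <- reduce_subnetwork(g, c("a", "c"))
  expect_equal(igraph::vcount(ends), 2)
  expect_equal(igraph::ecount(ends), 0)

  same <- reduce_subnetwork(g, c("a", "b", "c"))
  expect_equal(igraph::ecount(same), 2)
  expect_setequal(igraph::V(same)$name, c("a", "b", "c"))

  expect_warning(reduce_subnetwork(g, c("a", "zzz")), "absent")
  expect_warning(empty <- reduce_subnetwork(g, character(0)), "empty")
  expect_equal(igraph::vcount(suppressWarnings(empty)), 0)

  # idempotence and commutation with keep-set intersection
  r1 <- reduce_subnetwork(g, c("a", "b"))
  r2 <- reduce_subnetwork(r1, c("a", "b"))
  expect_true(igraph::identical_graphs(r1, r2))
  ab_then_b <- reduce_subnetwork(r1, "b")
  b_direct <- reduce_subnetwork(g, intersect(c("a", "b"), "b"))
  expect_setequal(igraph::V(ab_then_b)$name, igraph::V(b_direct)$name)
  expect_equal(igraph::ecount(ab_then_b), igraph::ecount(b_direct))
})

test_that("degree centrality is the raw incident-edge count", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  expect_equal(degree_centrality(tri)$degree, c(2L, 2L, 2L))

  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  deg <- degree_centrality(star)
  expect_equal(deg$degree[deg$gene == "hub"], 5L)
  expect_true(all(deg$degree[deg$gene != "hub"] == 1L))
})
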