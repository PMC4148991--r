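test_that("self-comparison recovers every gene at 100% identity", {
  set.seed(31)
  gs <- random_gene_set("G1", 12)
  gs2 <- relabel_gene_set(gs, "G2")
  orth <- detect_orthologs(gs, gs2)
  expect_equal(nrow(orth), 12L)
  expect_true(all(orth$protein_identity == 100))
  res <- compute_agios(gs, gs2)
  expect_equal(res$agios, 100)
  expect_equal(res$n_orthologs, length(gs))
  expect_true(all(res$per_pair$nucleotide_identity == 100))
})

test_that("unrelated random proteomes yield no ortholog calls", {
  set.seed(32)
  a <- random_gene_set("A", 20)
  b <- random_gene_set("B", 20)
  with_filter <- detect_orthologs(a, b)
  expect_equal(nrow(with_filter), 0L)
  # brute-force confirmation with the prefilter disabled: no pair passes
  # the identity/coverage thresholds either
  no_filter <- detect_orthologs(a, b, rbh_params(prefilter_kmer = NA))
  expect_equal(nrow(no_filter), 0L)
})

test_that("AGIOS recovers the simulator's realized identity and shared set", {
  sim <- simulate_pair(simulation_config(n_genes = 50, divergence_d = 0.05,
                                         gene_length_range = c(80, 200),
                                         seed = 33))
  res <- compute_agios(sim$set_a, sim$set_b)
  expect_equal(res$n_orthologs, 50L)
  expect_equal(sub("_A$", "", res$per_pair$gene_a),
               sub("_B$", "", res$per_pair$gene_b))
  expect_equal(sort(sub("_A$", "", res$per_pair$gene_a)),
               sort(sim$truth$shared_gene_ids))
  expect_lt(abs(res$agios - sim$truth$mean_realized_identity), 0.5)
})

test_that("AGIOS is symmetric and bounded", {
  sim <- simulate_pair(simulation_config(n_genes = 25, divergence_d = 0.10,
                                         gene_length_range = c(60, 120),
                                         seed = 34))
  ab <- compute_agios(sim$set_a, sim$set_b)
  ba <- compute_agios(sim$set_b, sim$set_a)
  expect_equal(ab$n_orthologs, ba$n_orthologs)
  expect_equal(ab$agios, ba$agios)
  expect_equal(ab$per_pair$gene_a, ba$per_pair$gene_b)
  expect_true(ab$agios >= 0 && ab$agios <= 100)
  expect_lte(ab$n_orthologs, min(length(sim$set_a), length(sim$set_b)))
})

test_that("the k-mer prefilter never changes the result on fixtures", {
  sim <- simulate_pair(simulation_config(n_genes = 15, divergence_d = 0.15,
                                         gene_length_range = c(60, 120),
                                         seed = 35))
  with_f <- compute_agios(sim$set_a, sim$set_b)
  without <- compute_agios(sim$set_a, sim$set_b,
                           params = rbh_params(prefilter_kmer = NA))
  expect_equal(with_f$per_pair, without$per_pair)
  expect_equal(with_f$agios, without$agios)
})

test_that("AGIOS with no orthologs is reported as missing, not zero", {
  set.seed(36)
  a <- random_gene_set("A", 5)
  b <- random_gene_set("B", 5)
  res <- compute_agios(a, b)
  expect_equal(res$n_orthologs, 0L)
  expect_true(is.na(res$agios))
})

test_that("length-weighted AGIOS is reported alongside when requested", {
  sim <- simulate_pair(simulation_config(n_genes = 10, divergence_d = 0.05,
                                         gene_length_range = c(50, 250),
                                         seed = 37))
  res <- compute_agios(sim$set_a, sim$set_b, weighted = TRUE)
  expect_false(is.null(res$agios_weighted))
  expect_true(abs(res$agios_weighted - res$agios) < 5)
})

test_that("the comparison matrix is consistent with pairwise results", {
  set.seed(38)
  gs <- random_gene_set("X", 8)
  genomes <- list(gs, relabel_gene_set(gs, "Y"), relabel_gene_set(gs, "Z"))
  mat <- agios_matrix(genomes)
  expect_equal(unname(mat$gene_counts), rep(8L, 3))
  off <- mat$agios_values[lower.tri(mat$agios_values)]
  expect_true(all(off == 100))
  expect_true(all(mat$ortholog_counts[lower.tri(mat$ortholog_counts)] == 8))
  # matrix entries equal the independent pairwise computation
  direct <- compute_agios(genomes[[1]], genomes[[2]])
  expect_equal(mat$agios_values["X", "Y"], direct$agios)
  expect_equal(mat$ortholog_counts["X", "Y"], as.numeric(direct$n_orthologs))
  # rendered grid: diagonal gene counts, upper orthologs, lower AGIOS
  grid <- format_agios_matrix(mat)
  expect_equal(grid["X", "X"], "8")
  expect_equal(grid["X", "Y"], "8")
  expect_equal(grid["Y", "X"], "100.00")
})

test_that("AGIOS ordering over a star phylogeny follows divergence", {
  star <- simulate_star(simulation_config(n_genes = 20,
                                          gene_length_range = c(60, 120),
                                          seed = 39),
                        divergences = c(0.02, 0.05, 0.10))
  mat <- agios_matrix(star$sets)
  # A is closest to B, then C: AGIOS(A,B) > AGIOS(A,C)
  expect_gt(mat$agios_values["A", "B"], mat$agios_values["A", "C"])
  expect_gt(mat$agios_values["A", "C"], mat$agios_values["B", "C"] - 1e-9)
  # matches the simulator's own pairwise identity ordering
  expect_equal(order(mat$agios_values["A", c("B", "C")]),
               order(star$pair_identity["A", c("B", "C")]))
})

test_that("duplicate genome labels are rejected", {
  set.seed(40)
  gs <- random_gene_set("X", 3)
  expect_error(agios_matrix(list(gs, gs)), "duplicate")
})
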