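# Synthetic-data generators: determinism, feasibility checks and planted
# structure.

test_that("gene tables are deterministic under a seed and respect n_nlr", {
  spec <- genome_spec(n_nlr = 12, n_planted_clusters = 2, seed = 101)
  g1 <- simulate_gene_table(spec)
  g2 <- simulate_gene_table(spec)
  expect_identical(g1, g2)
  expect_equal(sum(g1$is_nlr), 12L)
  expect_true(all(g1$start <= g1$end))
  expect_false(any(duplicated(g1$gene_id)))

  empty <- simulate_gene_table(genome_spec(n_nlr = 0, n_planted_clusters = 0,
                                           n_head_to_head = 0, seed = 1))
  expect_equal(sum(empty$is_nlr), 0L)
})

test_that("infeasible genome specs are rejected", {
  expect_error(genome_spec(n_nlr = 3, n_planted_clusters = 2,
                           cluster_size_range = c(2, 2), n_head_to_head = 0),
               "infeasible")
  expect_error(genome_spec(within_cluster_intervening = 9), "cluster definition")
  expect_error(genome_spec(gene_length_range = c(100, 50)), "non-empty")
  expect_error(simulate_gene_table(
    genome_spec(n_contigs = 1, genes_per_contig = 5,
                n_nlr = 6, n_planted_clusters = 2,
                cluster_size_range = c(3, 3), n_head_to_head = 0, seed = 1)),
    "infeasible")
})

test_that("planted clusters are recovered exactly by detection", {
  spec <- genome_spec(n_planted_clusters = 2, cluster_size_range = c(2, 2),
                      n_head_to_head = 0, n_nlr = 8, seed = 5)
  genes <- simulate_gene_table(spec)
  found <- detect_clusters(genes, cluster_params(40000, 8))
  expect_equal(nrow(found), 2L)
  expect_equal(sum(found$n_members), 4L)
  # brute-force oracle agrees
  want <- oracle_clusters(genes, 40000, 8)
  got <- found$member_ids
  expect_setequal(vapply(got, function(x) paste(sort(x), collapse = ","), character(1)),
                  vapply(want, function(x) paste(sort(x), collapse = ","), character(1)))
})

test_that("planted head-to-head pairs are adjacent divergent NLR clusters", {
  spec <- genome_spec(n_planted_clusters = 2, n_head_to_head = 2,
                      n_nlr = 12, seed = 9)
  genes <- simulate_gene_table(spec)
  found <- detect_clusters(genes)
  expect_equal(sum(found$head_to_head), 2L)
  h2h <- found[found$head_to_head, ]
  for (i in seq_len(nrow(h2h))) {
    expect_true(detect_head_to_head(h2h[i, ], genes))
  }
})

test_that("generated NB-ARC Walker B has an acidic residue right after the aspartate", {
  prot <- simulate_nb_proteins(20, "NB-ARC", seed = 21)
  after_d <- substring(prot$sequence, prot$walkerB_pos + 5, prot$walkerB_pos + 5)
  expect_true(all(after_d %in% c("D", "E")))
  at_d <- substring(prot$sequence, prot$walkerB_pos + 4, prot$walkerB_pos + 4)
  expect_true(all(at_d == "D"))
})

test_that("corrupting the Walker B breaks both consensus matches", {
  prot <- simulate_nb_protein(protein_spec("NB-ARC", corrupt_motif = TRUE, seed = 22))
  expect_equal(classify_walker_b(prot$sequence)$walkerB_type, "neither")
})

test_that("protein generation is deterministic and validates motif layout", {
  s1 <- simulate_nb_protein(protein_spec("T-NACHT", seed = 33))
  s2 <- simulate_nb_protein(protein_spec("T-NACHT", seed = 33))
  expect_identical(s1, s2)
  expect_error(protein_spec(walkerA_pos = 200, walkerB_pos = 100), "offsets")
  expect_error(protein_spec(walkerA_pos = 115, walkerB_pos = 120), "overlap")
  expect_error(protein_spec(heths_pos = 345, total_length = 350), "past the end")
})

test_that("simulated domain hits honour the plan and planted E-values", {
  genes <- simulate_gene_table(genome_spec(n_nlr = 5, n_planted_clusters = 0,
                                           n_head_to_head = 0, seed = 4))
  plan <- plan_tripartite(genes)
  hits <- simulate_domain_hits(plan, seed = 2)
  expect_equal(nrow(hits), nrow(plan))
  expect_true(all(hits$evalue >= 1e-30 & hits$evalue <= 1e-4))
  expect_identical(simulate_domain_hits(plan, seed = 2), hits)

  plan$evalue <- NA_real_
  plan$evalue[1] <- 1e-12
  hits2 <- simulate_domain_hits(plan, seed = 2)
  expect_equal(hits2$evalue[1], 1e-12)

  expect_equal(nrow(simulate_domain_hits(plan[0, ])), 0L)
})

test_that("Brownian traits: noise-free limit is exactly linear", {
  tr <- ape::rcoal(12)
  tt <- simulate_brownian_traits(tr, slope = 2, intercept = 1, sigma2 = 0, seed = 1)
  expect_equal(tt$y, 1 + 2 * tt$x)
  fit <- pgls_fit(tt, "x", "y", tr)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
})

test_that("Brownian traits on a star tree have iid residuals", {
  tr <- ape::stree(10, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  V <- ape::vcv(tr)
  expect_equal(unname(V), diag(10))
  tt <- simulate_brownian_traits(tr, 0, 0, 1, seed = 3)
  expect_equal(nrow(tt), 10L)
})

test_that("zero-length trees are rejected", {
  tr <- ape::rcoal(5)
  tr$edge.length[] <- 0
  expect_error(simulate_brownian_traits(tr, 1, 0, 1, seed = 1), "Zero-length")
})
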