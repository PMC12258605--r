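# NLR cluster detection, permutation null and parameter calibration.

two_nlr_table <- function(gap_bp, n_intervening, strands = c("+", "+")) {
  # two NLRs separated by `gap_bp` with `n_intervening` non-NLR genes
  # packed inside the gap
  g1_end <- 1000L
  g2_start <- g1_end + gap_bp + 1L
  rows <- list(
    tibble::tibble(gene_id = "nlr1", contig = "c1", start = 1L, end = g1_end,
                   strand = strands[1], is_nlr = TRUE))
  if (n_intervening > 0) {
    width <- max(1L, (gap_bp - 2L) %/% max(1L, n_intervening) - 2L)
    s <- g1_end + 2L
    for (i in seq_len(n_intervening)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = paste0("f", i), contig = "c1",
        start = as.integer(s), end = as.integer(s + width - 1L),
        strand = "+", is_nlr = FALSE)
      s <- s + width + 1L
    }
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    gene_id = "nlr2", contig = "c1", start = g2_start,
    end = g2_start + 1000L, strand = strands[2], is_nlr = TRUE)
  dplyr::bind_rows(rows)
}

test_that("gap and intervening-gene thresholds gate cluster membership", {
  # gaps 10 kb then 50 kb: only the first pair clusters
  g <- dplyr::bind_rows(
    two_nlr_table(10000, 0),
    dplyr::mutate(two_nlr_table(50000, 0),
                  gene_id = paste0(gene_id, "_b"),
                  start = start + 200000L, end = end + 200000L))
  cl <- detect_clusters(g, cluster_params(40000, 8))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 2L)
  expect_setequal(cl$member_ids[[1]], c("nlr1", "nlr2"))

  # single NLR: no cluster
  single <- tibble::tibble(gene_id = "n1", contig = "c1", start = 1L,
                           end = 1000L, strand = "+", is_nlr = TRUE)
  expect_equal(nrow(detect_clusters(single)), 0L)

  # 9 intervening genes veto the pair even at 5 kb
  g9 <- two_nlr_table(5000, 9)
  expect_equal(nrow(detect_clusters(g9, cluster_params(40000, 8))), 0L)
  # 8 intervening genes are allowed (inclusive threshold)
  g8 <- two_nlr_table(5000, 8)
  expect_equal(count_clustered(g8, cluster_params(40000, 8)), 2)
  # strict mode uses exclusive thresholds
  expect_equal(count_clustered(g8, cluster_params(40000, 8, strict = TRUE)), 0)
  expect_equal(count_clustered(two_nlr_table(40000, 0),
                               cluster_params(40000, 0, strict = TRUE)), 0)
})

test_that("detect_clusters equals the exhaustive run-enumeration oracle", {
  withr::with_seed(19, {
    for (i in 1:60) {
      genes <- random_gene_table(sample(10:50, 1), nlr_prob = 0.4,
                                 contigs = sample(1:3, 1))
      params <- cluster_params(sample(c(5000, 20000, 40000), 1), sample(0:8, 1))
      got <- detect_clusters(genes, params)$member_ids
      want <- oracle_clusters(genes, params$max_gap_bp, params$max_intervening)
      expect_setequal(vapply(got, paste, character(1), collapse = ","),
                      vapply(want, paste, character(1), collapse = ","))
      # cluster membership partitions clustered NLRs
      expect_false(any(duplicated(unlist(got))))
    }
  })
})

test_that("clustered count is monotone in both parameters", {
  withr::with_seed(23, {
    for (i in 1:20) {
      genes <- random_gene_table(40, nlr_prob = 0.35)
      c_small <- count_clustered(genes, cluster_params(10000, 2))
      c_gap <- count_clustered(genes, cluster_params(60000, 2))
      c_int <- count_clustered(genes, cluster_params(10000, 8))
      expect_gte(c_gap, c_small)
      expect_gte(c_int, c_small)
    }
  })
})

test_that("head-to-head detection uses divergent coordinate-order strands", {
  expect_true(detect_head_to_head(
    detect_clusters(two_nlr_table(5000, 0, c("-", "+")))[1, ],
    two_nlr_table(5000, 0, c("-", "+"))))
  for (ss in list(c("+", "+"), c("+", "-"), c("-", "-"))) {
    g <- two_nlr_table(5000, 0, ss)
    expect_false(detect_head_to_head(detect_clusters(g)[1, ], g))
  }
  # not applicable beyond pairs
  g3 <- simulate_gene_table(genome_spec(n_planted_clusters = 1,
                                        cluster_size_range = c(3, 3),
                                        n_head_to_head = 0, n_nlr = 3, seed = 2))
  cl <- detect_clusters(g3)
  expect_false(detect_head_to_head(cl[1, ], g3))
})

test_that("permutation null is deterministic and degenerate cases are forced", {
  genes <- simulate_gene_table(genome_spec(n_nlr = 10, seed = 31))
  n1 <- permutation_null(genes, n_perm = 50, seed = 99)
  n2 <- permutation_null(genes, n_perm = 50, seed = 99)
  expect_identical(n1$null_counts, n2$null_counts)

  # all genes NLR: every replicate equals the observed count
  all_nlr <- dplyr::mutate(random_gene_table(15), is_nlr = TRUE)
  pn <- permutation_null(all_nlr, n_perm = 20, seed = 1)
  expect_true(all(pn$null_counts == pn$observed))
  expect_equal(pn$excess, 0)
})

test_that("a planted tight cluster shows positive excess over the null", {
  withr::with_seed(37, {
    wins <- vapply(1:20, function(i) {
      genes <- simulate_gene_table(
        genome_spec(n_contigs = 4, genes_per_contig = 150, n_nlr = 6,
                    n_planted_clusters = 2, cluster_size_range = c(3, 3),
                    n_head_to_head = 0, seed = sample.int(1e6, 1)))
      pn <- permutation_null(genes, n_perm = 60, seed = sample.int(1e6, 1))
      pn$excess > 0
    }, logical(1))
    expect_gte(mean(wins), 0.95)
  })
})

test_that("calibration selects the forced grid point and breaks ties towards smaller", {
  # genome whose excess is uniquely maximal at (40 kb, 8): plant a pair at
  # a 35 kb gap with 8 intervening genes in an otherwise sparse genome
  genes <- dplyr::bind_rows(
    two_nlr_table(35000, 8),
    tibble::tibble(gene_id = sprintf("far%02d", 1:30), contig = "c2",
                   start = as.integer(seq(1, by = 100000, length.out = 30)),
                   end = as.integer(seq(1, by = 100000, length.out = 30) + 1000),
                   strand = "+", is_nlr = FALSE))
  cal <- calibrate_params(list(genes), gap_grid = c(20000, 35000, 40000),
                          intervening_grid = c(2, 8), n_perm = 30, seed = 5)
  expect_equal(cal$selected$max_gap_bp, 35000)
  expect_equal(cal$selected$max_intervening, 8L)

  # tie rule: identical scores resolve to smaller gap then intervening
  genes2 <- two_nlr_table(1000, 0)
  cal2 <- calibrate_params(list(genes2), gap_grid = c(5000, 10000),
                           intervening_grid = c(0, 1), n_perm = 10, seed = 6)
  expect_equal(cal2$selected$max_gap_bp, 5000)
  expect_equal(cal2$selected$max_intervening, 0L)

  expect_error(calibrate_params(list()), "at least one genome")
})
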