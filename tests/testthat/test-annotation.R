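# Domain-hit resolution, category mapping, NLR calling and architecture
# classification.

make_hits <- function(...) {
  rows <- list(...)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(gene_id = r[[1]], profile = r[[2]], source = r[[3]],
                   aa_start = r[[4]], aa_end = r[[5]], evalue = r[[6]],
                   score = 100)
  })
}

test_that("same-source NB competitions follow the squared-E-value rule", {
  # best E-value beats the square of its competitor: resolved
  h <- make_hits(list("g1", "NACHT", "sordariales_specific", 100, 400, 1e-10),
                 list("g1", "NB-ARC", "sordariales_specific", 120, 420, 1e-4))
  r <- resolve_competing_hits(h)
  expect_equal(nrow(r), 1L)
  expect_equal(r$profile, "NACHT")
  expect_equal(r$status, "resolved")

  # 1e-6 is not below (1e-4)^2 = 1e-8: NB present but undetermined
  h2 <- make_hits(list("g1", "NACHT", "sordariales_specific", 100, 400, 1e-6),
                  list("g1", "NB-ARC", "sordariales_specific", 120, 420, 1e-4))
  r2 <- resolve_competing_hits(h2)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$status, "undetermined")
  expect_equal(r2$category, "NB-undetermined")

  # decoy pair: 1e-12 < (1e-5)^2 = 1e-10, best retained
  h3 <- make_hits(list("g1", "NACHT", "sordariales_specific", 100, 400, 1e-12),
                  list("g1", "NB-ARC", "sordariales_specific", 100, 400, 1e-5))
  expect_equal(resolve_competing_hits(h3)$profile, "NACHT")
})

test_that("non-NB same-source stand-offs keep all predictions", {
  h <- make_hits(list("g1", "HeLo", "pfam_a", 1, 120, 1e-6),
                 list("g1", "Goodbye", "pfam_a", 10, 130, 1e-5))
  r <- resolve_competing_hits(h)
  expect_equal(nrow(r), 2L)
  expect_true(all(r$status == "multiple"))
})

test_that("source priority wins outright over E-values", {
  h <- make_hits(list("g1", "HeLo", "wojciechowski", 1, 120, 1e-3),
                 list("g1", "Goodbye", "pfam_a", 10, 130, 1e-20))
  r <- resolve_competing_hits(h)
  expect_equal(nrow(r), 1L)
  expect_equal(r$source, "wojciechowski")
})

test_that("single and non-overlapping hits pass through resolved", {
  h <- make_hits(list("g1", "NACHT", "pfam_a", 100, 400, 1e-9))
  expect_equal(resolve_competing_hits(h)$status, "resolved")

  h2 <- make_hits(list("g1", "HeLo", "pfam_a", 1, 100, 1e-9),
                  list("g1", "NACHT", "pfam_a", 200, 500, 1e-9))
  expect_equal(nrow(resolve_competing_hits(h2)), 2L)
})

test_that("overlap must reach the fraction of the shorter interval", {
  # 30 aa overlap of a 100-aa and a 300-aa hit: 30% of the shorter
  h <- make_hits(list("g1", "NACHT", "pfam_a", 1, 100, 1e-6),
                 list("g1", "NB-ARC", "pfam_a", 71, 370, 1e-4))
  expect_equal(nrow(resolve_competing_hits(h, overlap_fraction = 0.5)), 2L)
  r <- resolve_competing_hits(h, overlap_fraction = 0.25)
  expect_equal(nrow(r), 1L)
  expect_equal(r$status, "undetermined")
})

test_that("resolution is invariant to input row order", {
  withr::with_seed(17, {
    for (i in 1:10) {
      n <- sample(3:7, 1)
      h <- tibble::tibble(
        gene_id = sample(c("g1", "g2"), n, replace = TRUE),
        profile = sample(c("NACHT", "NB-ARC", "HeLo", "Ankyrin", "TPR"), n, replace = TRUE),
        source = sample(names(nlrscape:::SOURCE_PRIORITY), n, replace = TRUE),
        aa_start = sample(1:200, n),
        evalue = 10^-runif(n, 2, 20),
        score = 50
      )
      h$aa_end <- h$aa_start + sample(50:150, n)
      ref <- resolve_competing_hits(h)
      perm <- resolve_competing_hits(h[sample(n), ])
      expect_equal(ref, perm)
    }
  })
})

test_that("categorize_domain applies the canonical merges", {
  got <- categorize_domain(c("sesA", "NAD1", "Lipocalin_5", "HRAM"))
  expect_equal(got$category, c("HeLo-like", "Goodbye-like", "Lipocalin_5", "amyloid"))
  expect_equal(got$class, c("nterm", "nterm", "noncanonical", "nterm"))
})

test_that("call_nlr_candidates needs NB + downstream canonical C-terminal + length", {
  calls <- resolve_competing_hits(make_hits(
    list("gA", "NACHT", "pfam_a", 100, 400, 1e-9),
    list("gA", "Ankyrin", "pfam_a", 450, 600, 1e-6),
    list("gB", "NACHT", "pfam_a", 100, 400, 1e-9),
    list("gB", "Ankyrin", "pfam_a", 450, 600, 1e-6),
    list("gC", "NACHT", "pfam_a", 100, 400, 1e-9),
    list("gD", "Ankyrin", "pfam_a", 50, 200, 1e-9),
    list("gD", "NACHT", "pfam_a", 300, 600, 1e-6)))
  lens <- c(gA = 2400, gB = 999, gC = 2400, gD = 2400)
  expect_equal(call_nlr_candidates(calls, lens), "gA")
  expect_error(call_nlr_candidates(calls, lens[1:3]), "gD")
})

test_that("architecture classification covers the documented classes", {
  tri <- resolve_competing_hits(make_hits(
    list("g1", "HeLo", "pfam_a", 10, 120, 1e-9),
    list("g1", "NACHT", "pfam_a", 150, 450, 1e-9),
    list("g1", "WD40", "pfam_a", 500, 800, 1e-9)))
  expect_equal(classify_architecture(tri, 850)$architecture_class, "tripartite")

  # NB starting at aa 12: upstream region shorter than 20 aa, no N call
  trunc <- resolve_competing_hits(make_hits(
    list("g2", "NACHT", "pfam_a", 12, 300, 1e-9),
    list("g2", "Ankyrin", "pfam_a", 350, 600, 1e-9)))
  expect_equal(classify_architecture(trunc, 650)$architecture_class, "missing-N")

  # two distinct canonical N-terminal categories
  mixed <- resolve_competing_hits(make_hits(
    list("g3", "sesB", "pfam_a", 1, 100, 1e-9),
    list("g3", "HeLo", "pfam_a", 120, 240, 1e-9),
    list("g3", "NACHT", "pfam_a", 300, 600, 1e-9),
    list("g3", "TPR", "pfam_a", 650, 900, 1e-9)))
  expect_equal(classify_architecture(mixed, 950)$architecture_class, "mixed")

  # non-canonical domain on one side, canonical on the other
  noncanon <- resolve_competing_hits(make_hits(
    list("g4", "Lipocalin_5", "pfam_a", 10, 120, 1e-9),
    list("g4", "NACHT", "pfam_a", 150, 450, 1e-9),
    list("g4", "Ankyrin", "pfam_a", 500, 800, 1e-9)))
  res <- classify_architecture(noncanon, 850)
  expect_equal(res$architecture_class, "non-canonical")
  expect_equal(res$noncanonical_domains[[1]], "Lipocalin_5")

  # no call on a long N side: undetermined
  undet <- resolve_competing_hits(make_hits(
    list("g5", "NACHT", "pfam_a", 200, 500, 1e-9),
    list("g5", "Ankyrin", "pfam_a", 550, 800, 1e-9)))
  expect_equal(classify_architecture(undet, 850)$architecture_class, "undetermined")
})

test_that("merge_intervals matches a positional union oracle", {
  expect_equal(merge_intervals(data.frame(start = c(1, 50), end = c(100, 150))),
               tibble::tibble(start = 1, end = 150))
  expect_equal(merge_intervals(data.frame(start = c(1, 20), end = c(10, 30))),
               tibble::tibble(start = c(1, 20), end = c(10, 30)))
  got <- merge_intervals(data.frame(start = c(1, 5, 8, 20), end = c(5, 9, 12, 25)))
  expect_equal(got, tibble::tibble(start = c(1, 20), end = c(12, 25)))

  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(1:8, 1)
      s <- sample(1:60, n, replace = TRUE)
      e <- s + sample(0:15, n, replace = TRUE)
      got <- merge_intervals(data.frame(start = s, end = e))
      covered <- sort(unique(unlist(Map(seq, s, e))))
      oracle <- split(covered, cumsum(c(1, diff(covered) != 1)))
      expect_equal(got$start, vapply(oracle, min, numeric(1), USE.NAMES = FALSE))
      expect_equal(got$end, vapply(oracle, max, numeric(1), USE.NAMES = FALSE))
    }
  })
})

test_that("alignment hits are filtered on score, NB overlap and defects", {
  nb <- data.frame(start = 1000, end = 2000)
  hits <- tibble::tibble(
    start = c(900, 5000, 1500, 1500),
    end = c(1100, 5400, 2500, 2500),
    score = c(199, 500, 500, 500),
    stop_codon = c(FALSE, FALSE, FALSE, FALSE),
    frameshift = c(FALSE, FALSE, TRUE, FALSE))
  kept <- filter_alignment_hits(hits, nb, min_score = 200)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 1500)
})
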