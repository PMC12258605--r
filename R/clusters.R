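# NLR cluster detection on gene coordinate tables, permutation-null
# calibration of the (max gap, max intervening genes) parameters, and
# head-to-head pair detection.
#
# A cluster is a maximal run of two or more NLRs on one contig in which
# every consecutive NLR pair is separated by at most `max_gap_bp` and by
# at most `max_intervening` non-NLR genes (inclusive thresholds by
# default, matching the calibration grid semantics; `strict = TRUE` uses
# strictly-less-than). The standard parameterisation is 40 kb and eight
# non-NLR genes.

#' Cluster detection parameters
#'
#' @param max_gap_bp Maximum separation between consecutive NLRs in bp
#'   (facing gene boundaries, i.e. start of the downstream gene minus end
#'   of the upstream gene minus one; overlapping genes count as gap 0).
#' @param max_intervening Maximum number of non-NLR genes between
#'   consecutive NLRs.
#' @param strict If `TRUE`, thresholds are exclusive (`<` instead of `<=`).
#' @return A list of class `"cluster_params"`.
#' @export
cluster_params <- function(max_gap_bp = 40000, max_intervening = 8,
                           strict = FALSE) {
  stopifnot(max_gap_bp >= 0, max_intervening >= 0)
  structure(list(max_gap_bp = as.numeric(max_gap_bp),
                 max_intervening = as.integer(max_intervening),
                 strict = isTRUE(strict)),
            class = "cluster_params")
}

# Vectorised core: sorts the table once and returns the maximal runs of
# linked consecutive NLRs (row indices into the sorted table). Both
# detect_clusters() and count_clustered() build on this; the permutation
# null calls it tens of thousands of times, so it avoids per-group
# data-frame machinery.
cluster_runs <- function(genes, params, presorted = FALSE) {
  g <- as_tibble(genes)
  if (!presorted) g <- g[order(g$contig, g$start), , drop = FALSE]
  idx <- which(g$is_nlr)
  runs <- list()
  if (length(idx) >= 2) {
    up <- idx[-length(idx)]
    down <- idx[-1]
    same <- g$contig[up] == g$contig[down]
    gap <- pmax(0, g$start[down] - g$end[up] - 1)
    intervening <- down - up - 1L
    linked <- if (params$strict) {
      same & gap < params$max_gap_bp & intervening < params$max_intervening
    } else {
      same & gap <= params$max_gap_bp & intervening <= params$max_intervening
    }
    grp <- cumsum(c(TRUE, !linked))
    runs <- unname(split(idx, grp))
    runs <- runs[lengths(runs) >= 2]
  }
  list(genes = g, runs = runs)
}

#' Detect NLR clusters in a gene table
#'
#' @param genes A gene table: `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `is_nlr` (1-based inclusive coordinates; sortable by
#'   contig and start).
#' @param params A [cluster_params()].
#' @return A tibble with one row per cluster: `cluster_id`, `contig`,
#'   `start`, `end`, `n_members`, `member_ids` (list column) and
#'   `head_to_head` (`TRUE` for 2-member clusters in divergent
#'   orientation).
#' @examples
#' genes <- simulate_gene_table(genome_spec(seed = 1))
#' detect_clusters(genes, cluster_params())
#' @export
detect_clusters <- function(genes, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  cr <- cluster_runs(genes, params)
  if (length(cr$runs) == 0) {
    return(tibble(cluster_id = character(), contig = character(),
                  start = integer(), end = integer(), n_members = integer(),
                  member_ids = list(), head_to_head = logical()))
  }
  g <- cr$genes
  out <- purrr::map_dfr(cr$runs, function(r) {
    members <- g[r, , drop = FALSE]
    tibble(contig = members$contig[1],
           start = min(members$start), end = max(members$end),
           n_members = nrow(members),
           member_ids = list(members$gene_id),
           head_to_head = nrow(members) == 2 &&
             identical(members$strand, c("-", "+")))
  })
  out <- arrange(out, .data$contig, .data$start)
  mutate(out, cluster_id = sprintf("cluster_%03d", row_number()), .before = 1)
}

#' Count clustered NLR genes
#'
#' Total number of NLRs that belong to any cluster under `params`.
#'
#' @inheritParams detect_clusters
#' @return Integer count.
#' @export
count_clustered <- function(genes, params = cluster_params()) {
  sum(lengths(cluster_runs(genes, params)$runs))
}

#' Is a 2-member cluster organised head-to-head?
#'
#' Head-to-head means divergent 5'-to-5' orientation: in coordinate order,
#' the upstream gene on the minus strand and the downstream gene on the
#' plus strand. Clusters with other than two members are not applicable
#' and return `FALSE`.
#'
#' @param cluster One row of the output of [detect_clusters()] (or any
#'   list with `member_ids`).
#' @param genes The gene table the cluster was detected in.
#' @return Logical flag.
#' @export
detect_head_to_head <- function(cluster, genes) {
  ids <- unlist(cluster$member_ids)
  if (length(ids) != 2) return(FALSE)
  g <- arrange(filter(as_tibble(genes), .data$gene_id %in% ids), .data$start)
  identical(g$strand, c("-", "+"))
}

#' Permutation null for the number of clustered genes
#'
#' Re-labels, in each replicate, a uniform random subset of genes (of size
#' equal to the observed NLR count, drawn without replacement over all
#' genes) as "NLR" and recounts clustered genes, giving the null
#' distribution of the clustered count for gene sets of that size.
#'
#' @inheritParams detect_clusters
#' @param n_perm Number of replicates.
#' @param seed Integer seed.
#' @return A list of class `"cluster_null"`: `observed`, `null_counts`
#'   (length `n_perm`), `null_mean`, `null_sd`, `excess`
#'   (observed - null mean).
#' @export
permutation_null <- function(genes, params = cluster_params(),
                             n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 1)
  genes <- arrange(as_tibble(genes), .data$contig, .data$start)
  n_nlr <- sum(genes$is_nlr)
  if (n_nlr > nrow(genes)) abort("More NLRs than genes.")
  observed <- count_clustered(genes, params)
  fake <- genes  # already sorted; replicates only relabel is_nlr
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fake$is_nlr <- FALSE
      fake$is_nlr[sample.int(nrow(genes), n_nlr)] <- TRUE
      sum(lengths(cluster_runs(fake, params, presorted = TRUE)$runs))
    }, numeric(1))
  })
  structure(list(observed = observed, null_counts = null_counts,
                 null_mean = mean(null_counts), null_sd = sd(null_counts),
                 excess = observed - mean(null_counts)),
            class = "cluster_null")
}

#' @export
print.cluster_null <- function(x, ...) {
  cat(sprintf("Clustered NLRs: observed %d, null %.2f +/- %.2f (n = %d), excess %.2f\n",
              x$observed, x$null_mean, x$null_sd, length(x$null_counts), x$excess))
  invisible(x)
}

# The calibration grid of candidate maximum inter-NLR distances (bp).
default_gap_grid <- function() {
  1000 * c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 6, 7, 8, 9, 10,
           15, 20, 25, 30, 35, 40, 45, 50, 100, 150, 200)
}

#' Calibrate cluster parameters against a permutation null
#'
#' For every genome and every (gap, intervening) grid point, computes the
#' excess of observed clustered NLRs over the permutation-null mean. A
#' grid point scores the fraction of genomes at which it attains that
#' genome's maximal excess; the highest-scoring point is selected, ties
#' broken towards smaller gap, then smaller intervening count.
#'
#' @param genomes A list of gene tables (one per genome).
#' @param gap_grid Candidate `max_gap_bp` values (default: 27 values from
#'   0 to 200 kb).
#' @param intervening_grid Candidate `max_intervening` values (default
#'   0:8).
#' @param n_perm Permutation replicates per genome and grid point.
#' @param seed Integer seed.
#' @return A list of class `"cluster_calibration"`: `selected` (a
#'   [cluster_params()]), `scores` (tibble of grid point scores) and
#'   `excess` (per-genome, per-grid-point excess tibble).
#' @export
calibrate_params <- function(genomes, gap_grid = default_gap_grid(),
                             intervening_grid = 0:8, n_perm = 100,
                             seed = NULL) {
  if (length(genomes) == 0) abort("Need at least one genome.")
  stopifnot(length(gap_grid) > 0, length(intervening_grid) > 0)
  grid <- tidyr::expand_grid(max_gap_bp = sort(gap_grid),
                             max_intervening = sort(intervening_grid))
  # Common random numbers: the same n_perm random gene subsets are reused
  # for every grid point of a genome, so grid points that behave
  # identically get exactly equal excess and the deterministic tie-break
  # applies, rather than Monte-Carlo noise picking a winner.
  excess <- with_seed(seed, {
    purrr::imap_dfr(genomes, function(genes, gi) {
      g <- as_tibble(genes)
      g <- g[order(g$contig, g$start), , drop = FALSE]
      n_nlr <- sum(g$is_nlr)
      if (n_nlr > nrow(g)) abort("More NLRs than genes.")
      subsets <- lapply(seq_len(n_perm), function(i) sample.int(nrow(g), n_nlr))
      purrr::pmap_dfr(grid, function(max_gap_bp, max_intervening) {
        params <- cluster_params(max_gap_bp, max_intervening)
        observed <- sum(lengths(cluster_runs(g, params, presorted = TRUE)$runs))
        fake <- g
        null_counts <- vapply(subsets, function(ss) {
          fake$is_nlr <- FALSE
          fake$is_nlr[ss] <- TRUE
          sum(lengths(cluster_runs(fake, params, presorted = TRUE)$runs))
        }, numeric(1))
        tibble(genome = as.character(gi), max_gap_bp = max_gap_bp,
               max_intervening = max_intervening, observed = observed,
               null_mean = mean(null_counts),
               excess = observed - mean(null_counts))
      })
    })
  })
  scores <- excess |>
    group_by(.data$genome) |>
    mutate(at_max = .data$excess >= max(.data$excess) - 1e-9) |>
    ungroup() |>
    group_by(.data$max_gap_bp, .data$max_intervening) |>
    summarise(score = mean(.data$at_max), .groups = "drop") |>
    arrange(dplyr::desc(.data$score), .data$max_gap_bp, .data$max_intervening)
  sel <- scores[1, ]
  structure(list(selected = cluster_params(sel$max_gap_bp, sel$max_intervening),
                 scores = scores, excess = excess),
            class = "cluster_calibration")
}

#' @export
print.cluster_calibration <- function(x, ...) {
  cat(sprintf("Selected cluster parameters: max gap %.0f bp, max intervening %d (score %.2f)\n",
              x$selected$max_gap_bp, x$selected$max_intervening,
              x$scores$score[1]))
  invisible(x)
}

#' Plot a cluster-parameter calibration surface
#'
#' Heatmap of grid-point scores (fraction of genomes at which the grid
#' point attains the genome's maximal excess over the permutation null).
#'
#' @param object A `cluster_calibration` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_calibration <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(factor(.data$max_gap_bp / 1000),
                               factor(.data$max_intervening),
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "max inter-NLR distance (kb)",
                  y = "max intervening non-NLR genes",
                  fill = "score",
                  title = "Cluster-parameter calibration against permutation null")
}
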