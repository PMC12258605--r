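# Simulators for every input the pipeline consumes: gene tables with
# planted NLR clusters and head-to-head pairs, NB proteins with planted
# Walker A / Walker B / HETHS motifs, domain-hit tables, and
# Brownian-motion trait data on a phylogeny.
#
# The generators are bit-reproducible under `seed` and construct inputs
# whose planted structure is exactly recoverable by the corresponding
# downstream operation when corruption is off: planted clusters satisfy the
# (40 kb, 8 intervening genes) cluster definition, blocks of NLR genes are
# separated by enough filler genes that no unplanted cluster can arise, and
# protein backgrounds are resampled until no spurious motif instance
# appears outside the planted windows.

#' Specification of a synthetic genome gene table
#'
#' @param n_contigs Number of contigs.
#' @param genes_per_contig Genes per contig.
#' @param gene_length_range Length-2 integer vector, gene span in bp.
#' @param intergenic_gap_range Length-2 integer vector, gap between
#'   consecutive genes in bp.
#' @param n_nlr Total number of NLR genes (clustered + isolated).
#' @param n_planted_clusters Number of planted NLR clusters (in addition to
#'   head-to-head pairs, which are planted as their own 2-gene clusters).
#' @param cluster_size_range Length-2 integer vector, members per planted
#'   cluster (each at least 2).
#' @param within_cluster_gap_bp Maximum separation in bp between two
#'   consecutive NLRs of a planted cluster; must not exceed 40000 so that
#'   planted clusters satisfy the standard cluster definition.
#' @param within_cluster_intervening Number of non-NLR genes between
#'   consecutive NLRs of a planted cluster (at most 8).
#' @param n_head_to_head Number of planted head-to-head pairs: adjacent
#'   NLR pairs in divergent (- then +) orientation.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `"genome_spec"`.
#' @export
genome_spec <- function(n_contigs = 5, genes_per_contig = 120,
                        gene_length_range = c(500L, 2500L),
                        intergenic_gap_range = c(200L, 2000L),
                        n_nlr = 20, n_planted_clusters = 3,
                        cluster_size_range = c(2L, 4L),
                        within_cluster_gap_bp = 40000,
                        within_cluster_intervening = 2,
                        n_head_to_head = 1, seed = NULL) {
  spec <- list(n_contigs = as.integer(n_contigs),
               genes_per_contig = as.integer(genes_per_contig),
               gene_length_range = as.integer(gene_length_range),
               intergenic_gap_range = as.integer(intergenic_gap_range),
               n_nlr = as.integer(n_nlr),
               n_planted_clusters = as.integer(n_planted_clusters),
               cluster_size_range = as.integer(cluster_size_range),
               within_cluster_gap_bp = as.numeric(within_cluster_gap_bp),
               within_cluster_intervening = as.integer(within_cluster_intervening),
               n_head_to_head = as.integer(n_head_to_head),
               seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_genome_spec(spec)
  structure(spec, class = "genome_spec")
}

validate_genome_spec <- function(spec) {
  with(spec, {
    if (n_contigs < 1 || genes_per_contig < 1) abort("Need at least one contig and one gene per contig.")
    if (diff(gene_length_range) < 0 || diff(intergenic_gap_range) < 0)
      abort("Ranges must be non-empty (low <= high).")
    if (any(intergenic_gap_range < 0)) abort("Gaps must be >= 0.")
    if (any(gene_length_range < 1)) abort("Gene lengths must be positive.")
    if (any(cluster_size_range < 2)) abort("Planted clusters need at least 2 members.")
    if (within_cluster_intervening > 8)
      abort("within_cluster_intervening > 8: planted clusters would violate the cluster definition.")
    if (within_cluster_gap_bp > 40000)
      abort("within_cluster_gap_bp > 40000: planted clusters would violate the cluster definition.")
    max_sep <- within_cluster_intervening * max(gene_length_range) +
      (within_cluster_intervening + 1) * max(intergenic_gap_range)
    if (max_sep > within_cluster_gap_bp)
      abort("Gene lengths / gaps too large for `within_cluster_gap_bp`; shrink ranges or intervening count.")
    max_clustered <- n_planted_clusters * max(cluster_size_range) + 2L * n_head_to_head
    min_clustered <- n_planted_clusters * min(cluster_size_range) + 2L * n_head_to_head
    if (min_clustered > n_nlr)
      abort("Spec infeasible: more clustered NLRs than `n_nlr`.")
    invisible(NULL)
  })
}

#' Simulate a gene coordinate table with planted NLR clusters
#'
#' Generates an ordered gene table (1-based inclusive coordinates, one row
#' per gene) in which `n_planted_clusters` NLR clusters, `n_head_to_head`
#' divergent NLR pairs and the remaining isolated NLRs are planted such
#' that [detect_clusters()] at the standard (40 kb, 8) parameters recovers
#' exactly the planted clusters. Blocks of NLR genes are separated by at
#' least nine filler genes, so no unplanted cluster can form. Planted
#' non-head-to-head 2-gene clusters are never given the divergent (-,+)
#' orientation, so [detect_head_to_head()] flags exactly the planted pairs.
#'
#' @param spec A [genome_spec()].
#' @return A tibble with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `is_nlr` and `planted_cluster` (cluster label, `NA` for
#'   genes outside planted clusters), sorted by contig and start.
#' @examples
#' genes <- simulate_gene_table(genome_spec(seed = 1))
#' dplyr::count(genes, is_nlr)
#' @export
simulate_gene_table <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  validate_genome_spec(spec)
  with_seed(spec$seed, {
    # Per-contig base layout of non-NLR genes.
    contigs <- purrr::map(seq_len(spec$n_contigs), function(ci) {
      g <- spec$genes_per_contig
      len <- sample_int_range(spec$gene_length_range[1], spec$gene_length_range[2], g)
      gap <- sample_int_range(spec$intergenic_gap_range[1], spec$intergenic_gap_range[2], g)
      start <- cumsum(gap) + cumsum(c(0L, head(len, -1L)))
      tibble(
        gene_id = sprintf("c%02d_g%04d", ci, seq_len(g)),
        contig = sprintf("contig_%02d", ci),
        start = as.integer(start),
        end = as.integer(start + len - 1L),
        strand = sample(c("+", "-"), g, replace = TRUE),
        is_nlr = FALSE,
        planted_cluster = NA_character_
      )
    })

    # Block plan: clusters, head-to-head pairs, isolated NLRs.
    sizes <- if (spec$n_planted_clusters > 0)
      sample_int_range(spec$cluster_size_range[1], spec$cluster_size_range[2],
                       spec$n_planted_clusters) else integer(0)
    # Trim cluster sizes if the draw overshoots the NLR budget.
    while (sum(sizes) + 2L * spec$n_head_to_head > spec$n_nlr) {
      i <- which(sizes > spec$cluster_size_range[1])[1]
      if (is.na(i)) abort("Spec infeasible: more clustered NLRs than `n_nlr`.")
      sizes[i] <- sizes[i] - 1L
    }
    n_isolated <- spec$n_nlr - sum(sizes) - 2L * spec$n_head_to_head
    m <- spec$within_cluster_intervening
    blocks <- c(
      purrr::map(seq_along(sizes), function(i) list(
        label = sprintf("cluster_%02d", i), k = sizes[i], intervening = m,
        head_to_head = FALSE)),
      purrr::map(seq_len(spec$n_head_to_head), function(i) list(
        label = sprintf("h2h_%02d", i), k = 2L, intervening = 0L,
        head_to_head = TRUE)),
      purrr::map(seq_len(n_isolated), function(i) list(
        label = NA_character_, k = 1L, intervening = 0L, head_to_head = FALSE))
    )
    if (length(blocks) > 0) blocks <- blocks[sample(length(blocks))]

    # Greedy placement: blocks are laid down contig by contig, separated by
    # nine filler genes so that no two blocks can be linked under any
    # intervening threshold <= 8.
    sep <- 9L
    cursor <- rep(1L, spec$n_contigs)
    for (b in blocks) {
      w <- b$k + (b$k - 1L) * b$intervening
      ci <- which(cursor + w - 1L <= spec$genes_per_contig)
      if (length(ci) == 0)
        abort("Spec infeasible: not enough genes to place all NLR blocks (increase genes_per_contig or n_contigs).")
      ci <- ci[which.max(spec$genes_per_contig - cursor[ci])]  # most room left
      idx0 <- cursor[ci]
      nlr_idx <- idx0 + (seq_len(b$k) - 1L) * (b$intervening + 1L)
      contigs[[ci]]$is_nlr[nlr_idx] <- TRUE
      contigs[[ci]]$planted_cluster[idx0:(idx0 + w - 1L)] <-
        if (b$k >= 2) b$label else NA_character_
      if (b$head_to_head) {
        contigs[[ci]]$strand[nlr_idx] <- c("-", "+")
      } else if (b$k == 2L) {
        # Avoid the divergent orientation so only planted pairs read head-to-head.
        pick <- sample(c("++", "--", "+-"), 1)
        contigs[[ci]]$strand[nlr_idx] <- strsplit(pick, "")[[1]]
      }
      cursor[ci] <- idx0 + w + sep
    }
    out <- bind_rows(contigs)
    out$planted_cluster[!out$is_nlr & !is.na(out$planted_cluster)] <- NA_character_
    arrange(out, .data$contig, .data$start)
  })
}

#' Specification of a synthetic NB-domain protein
#'
#' Layout follows the canonical NB-domain organisation: Walker A (P-loop,
#' `GxxxxGK[ST]`) N-terminal of the Walker B, with the HETHS helical
#' region C-terminal of the Walker B. Defaults give a 350-aa domain with
#' motifs at realistic relative positions.
#'
#' @param nb_type `"T-NACHT"`, `"N-NACHT"` or `"NB-ARC"`.
#' @param total_length Protein length (aa).
#' @param walkerA_pos,walkerB_pos,heths_pos 1-based motif start offsets;
#'   must be increasing and leave room for full motif instances.
#' @param background_alphabet Residues for the background (default: the 20
#'   standard amino acids, uniform).
#' @param corrupt_motif If `TRUE`, one position of the planted Walker B is
#'   mutated so that neither Walker B consensus matches.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `"protein_spec"`.
#' @export
protein_spec <- function(nb_type = c("T-NACHT", "N-NACHT", "NB-ARC"),
                         total_length = 350, walkerA_pos = 30,
                         walkerB_pos = 120, heths_pos = 220,
                         background_alphabet = AA20,
                         corrupt_motif = FALSE, seed = NULL) {
  nb_type <- match.arg(nb_type)
  spec <- list(nb_type = nb_type, total_length = as.integer(total_length),
               walkerA_pos = as.integer(walkerA_pos),
               walkerB_pos = as.integer(walkerB_pos),
               heths_pos = as.integer(heths_pos),
               background_alphabet = background_alphabet,
               corrupt_motif = isTRUE(corrupt_motif),
               seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_protein_spec(spec)
  structure(spec, class = "protein_spec")
}

motif_span <- function(motif) length(parse_motif(motif))

validate_protein_spec <- function(spec) {
  wa_len <- motif_span(MOTIF_WALKER_A)
  wb_len <- motif_span(if (spec$nb_type == "NB-ARC") MOTIF_WALKER_B_NBARC else MOTIF_WALKER_B_NACHT)
  he_len <- motif_span(MOTIF_HETHS_NAIP)
  if (!(spec$walkerA_pos < spec$walkerB_pos && spec$walkerB_pos < spec$heths_pos &&
        spec$heths_pos < spec$total_length))
    abort("Motif offsets must satisfy walkerA_pos < walkerB_pos < heths_pos < total_length.")
  if (spec$walkerA_pos + wa_len > spec$walkerB_pos)
    abort("Walker A and Walker B motif windows overlap.")
  if (spec$walkerB_pos + wb_len > spec$heths_pos)
    abort("Walker B and HETHS motif windows overlap.")
  if (spec$heths_pos + he_len - 1L > spec$total_length)
    abort("HETHS window extends past the end of the protein.")
  invisible(NULL)
}

# Check that a candidate sequence realises exactly the planted motif
# layout: the planted Walker B (and, for NACHT types, HETHS) instance at
# its offset and no spurious instance anywhere else, so the planted type
# is recovered with certainty by the motif classifiers.
planted_layout_ok <- function(s, spec) {
  nacht <- match_motif(s, MOTIF_WALKER_B_NACHT)$aa_start
  nbarc <- match_motif(s, MOTIF_WALKER_B_NBARC)$aa_start
  naip <- match_motif(s, MOTIF_HETHS_NAIP)$aa_start
  if (spec$corrupt_motif) return(length(nacht) == 0 && length(nbarc) == 0)
  if (spec$nb_type == "NB-ARC")
    return(length(nacht) == 0 && identical(nbarc, spec$walkerB_pos) &&
             length(naip) == 0)
  if (!identical(nacht, spec$walkerB_pos)) return(FALSE)
  if (spec$nb_type == "N-NACHT") identical(naip, spec$heths_pos)
  else length(naip) == 0
}

# Draw one literal instance of a degenerate motif.
instantiate_motif <- function(motif, hydrophobic = DEFAULT_HYDROPHOBIC) {
  pat <- parse_motif(motif, hydrophobic)
  paste(vapply(pat, function(p) {
    if (identical(p, "*")) sample(AA20, 1) else sample(rep(p, 2), 1)
  }, character(1)), collapse = "")
}

#' Simulate an NB-domain protein with planted motifs
#'
#' Plants a Walker A instance, a type-specific Walker B instance and (for
#' NACHT types) a HETHS instance at the offsets in `spec`, on a uniform
#' random background. The HETHS block matches the NAIP-like consensus only
#' for `nb_type = "N-NACHT"`; for T-NACHT the glutamine of the consensus is
#' replaced so the NAIP motif does not match. With `corrupt_motif = TRUE`
#' the first aspartate of the Walker B is mutated to lysine, breaking both
#' Walker B consensi. The background is resampled until no spurious Walker
#' B or NAIP-HETHS instance occurs outside the planted windows, so the
#' planted type is recovered exactly by [type_nb_domain()].
#'
#' @param spec A [protein_spec()].
#' @return A one-row tibble: `nb_type`, `sequence`, `walkerA_pos`,
#'   `walkerB_pos`, `heths_pos` (`NA` for NB-ARC), `corrupt_motif`.
#' @examples
#' simulate_nb_protein(protein_spec("N-NACHT", seed = 1))
#' @export
simulate_nb_protein <- function(spec) {
  stopifnot(inherits(spec, "protein_spec"))
  validate_protein_spec(spec)
  with_seed(spec$seed, {
    wb_motif <- if (spec$nb_type == "NB-ARC") MOTIF_WALKER_B_NBARC else MOTIF_WALKER_B_NACHT
    wa <- instantiate_motif(MOTIF_WALKER_A)
    wb <- instantiate_motif(wb_motif)
    if (spec$corrupt_motif) {
      # Mutate the first aspartate (motif position 5) to lysine: not acidic,
      # not G/A/S, not hydrophobic -- both consensi are broken.
      substr(wb, 5, 5) <- "K"
    }
    he <- NULL
    if (spec$nb_type != "NB-ARC") {
      he <- instantiate_motif(MOTIF_HETHS_NAIP)
      if (spec$nb_type == "T-NACHT") substr(he, 7, 7) <- "K"  # break Q of QE
    }
    planted <- list(list(pos = spec$walkerA_pos, block = wa),
                    list(pos = spec$walkerB_pos, block = wb))
    if (!is.null(he)) planted <- c(planted, list(list(pos = spec$heths_pos, block = he)))

    assemble <- function() {
      chars <- sample(spec$background_alphabet, spec$total_length, replace = TRUE)
      for (p in planted) {
        chars[p$pos:(p$pos + nchar(p$block) - 1L)] <- strsplit(p$block, "")[[1]]
      }
      paste(chars, collapse = "")
    }
    seq <- NULL
    for (try in 1:100) {
      s <- assemble()
      if (planted_layout_ok(s, spec)) { seq <- s; break }
    }
    if (is.null(seq))
      abort("Could not assemble a sequence free of spurious motif instances; check the spec.")
    tibble(nb_type = spec$nb_type, sequence = seq,
           walkerA_pos = spec$walkerA_pos, walkerB_pos = spec$walkerB_pos,
           heths_pos = if (spec$nb_type == "NB-ARC") NA_integer_ else spec$heths_pos,
           corrupt_motif = spec$corrupt_motif)
  })
}

#' Simulate a set of NB-domain proteins of one type
#'
#' @param n Number of proteins.
#' @param nb_type,corrupt_motif Passed to [protein_spec()].
#' @param seed Integer seed for the whole set.
#' @param ... Further arguments to [protein_spec()].
#' @return A tibble with `gene_id` plus the columns of
#'   [simulate_nb_protein()].
#' @export
simulate_nb_proteins <- function(n, nb_type, corrupt_motif = FALSE,
                                 seed = NULL, ...) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      simulate_nb_protein(protein_spec(nb_type, corrupt_motif = corrupt_motif,
                                       seed = NULL, ...))
    }) |>
      mutate(gene_id = sprintf("%s_%04d", gsub("-", "", tolower(nb_type)),
                               seq_len(n)), .before = 1)
  })
}

#' Simulate a homologous family of NB-domain proteins
#'
#' Unlike [simulate_nb_proteins()], whose backgrounds are independent
#' random sequences, this generator emulates the homology structure of a
#' real NB-domain family: all proteins of a call derive from one
#' type-specific ancestral sequence by independent point substitutions at
#' rate `divergence`, with the type's motif instances planted on top (and
#' the same no-spurious-instance guarantee). Sequences of one family
#' therefore share both their motif blocks and family-wide background
#' similarity, while different families are unrelated -- the situation in
#' which alignment-free ordination separates NB types.
#'
#' @param n Number of proteins.
#' @param nb_type `"T-NACHT"`, `"N-NACHT"` or `"NB-ARC"`.
#' @param divergence Per-site substitution probability from the family
#'   ancestor (default 0.35, i.e. roughly 65% within-family identity).
#' @param seed Integer seed.
#' @param ... Further arguments to [protein_spec()].
#' @return A tibble as [simulate_nb_proteins()].
#' @export
simulate_nb_family <- function(n, nb_type, divergence = 0.35, seed = NULL, ...) {
  stopifnot(divergence >= 0, divergence <= 1)
  with_seed(seed, {
    spec <- protein_spec(nb_type, seed = NULL, ...)
    ancestor <- sample(spec$background_alphabet, spec$total_length, replace = TRUE)
    wb_motif <- if (nb_type == "NB-ARC") MOTIF_WALKER_B_NBARC else MOTIF_WALKER_B_NACHT
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      wb <- instantiate_motif(wb_motif)
      he <- NULL
      if (nb_type != "NB-ARC") {
        he <- instantiate_motif(MOTIF_HETHS_NAIP)
        if (nb_type == "T-NACHT") substr(he, 7, 7) <- "K"
      }
      for (try in 1:100) {
        chars <- ancestor
        mut <- runif(spec$total_length) < divergence
        chars[mut] <- sample(spec$background_alphabet, sum(mut), replace = TRUE)
        chars[spec$walkerA_pos:(spec$walkerA_pos + motif_span(MOTIF_WALKER_A) - 1L)] <-
          strsplit(instantiate_motif(MOTIF_WALKER_A), "")[[1]]
        chars[spec$walkerB_pos:(spec$walkerB_pos + nchar(wb) - 1L)] <-
          strsplit(wb, "")[[1]]
        if (!is.null(he)) {
          chars[spec$heths_pos:(spec$heths_pos + nchar(he) - 1L)] <-
            strsplit(he, "")[[1]]
        }
        s <- paste(chars, collapse = "")
        if (planted_layout_ok(s, spec)) {
          return(tibble(nb_type = nb_type, sequence = s,
                        walkerA_pos = spec$walkerA_pos,
                        walkerB_pos = spec$walkerB_pos,
                        heths_pos = if (nb_type == "NB-ARC") NA_integer_ else spec$heths_pos,
                        corrupt_motif = FALSE))
        }
      }
      abort("Could not assemble a family member free of spurious motif instances.")
    })
    mutate(rows, gene_id = sprintf("%s_fam_%04d", gsub("-", "", tolower(nb_type)),
                                   seq_len(n)), .before = 1)
  })
}

#' Build a tripartite architecture plan for a gene table
#'
#' Produces, for every NLR-flagged gene, one N-terminal hit, one NB hit and
#' one C-terminal hit at non-overlapping regions of the encoded protein
#' (length = gene span / 3), ready for [simulate_domain_hits()].
#'
#' @param gene_table A gene table as from [simulate_gene_table()].
#' @param nterm_profile,nb_profile,cterm_profile Profile names for the
#'   three regions.
#' @param source Hit source for all rows.
#' @return A plan tibble: `gene_id`, `profile`, `source`, `aa_start`,
#'   `aa_end`.
#' @export
plan_tripartite <- function(gene_table, nterm_profile = "HET",
                            nb_profile = "NACHT", cterm_profile = "Ankyrin",
                            source = "sordariales_specific") {
  nlr <- filter(as_tibble(gene_table), .data$is_nlr)
  purrr::map_dfr(seq_len(nrow(nlr)), function(i) {
    plen <- max(90L, (nlr$end[i] - nlr$start[i] + 1L) %/% 3L)
    third <- plen %/% 3L
    tibble(gene_id = nlr$gene_id[i],
           profile = c(nterm_profile, nb_profile, cterm_profile),
           source = source,
           aa_start = c(5L, third + 5L, 2L * third + 5L),
           aa_end = c(third - 5L, 2L * third - 5L, plen - 2L))
  })
}

#' Simulate a domain-hit table from an architecture plan
#'
#' Turns a plan (one row per wanted hit) into a domain-hit table in the
#' column layout of [read_domtblout()]. E-values are drawn log-uniformly
#' from `evalue_range`, spanning realistic hmmsearch magnitudes; a plan row
#' may carry its own `evalue` column (non-`NA` values are used verbatim),
#' which is how decoy hits with controlled E-value ratios are planted.
#'
#' @param plan A tibble with columns `gene_id`, `profile`, `source`,
#'   `aa_start`, `aa_end` and optionally `evalue`.
#' @param evalue_range Length-2 numeric, sampling range for E-values.
#' @param seed Integer seed.
#' @return A domain-hit tibble: `gene_id`, `profile`, `source`, `aa_start`,
#'   `aa_end`, `evalue`, `score`.
#' @export
simulate_domain_hits <- function(plan, evalue_range = c(1e-30, 1e-4),
                                 seed = NULL) {
  plan <- as_tibble(plan)
  if (nrow(plan) == 0) {
    return(tibble(gene_id = character(), profile = character(),
                  source = character(), aa_start = integer(),
                  aa_end = integer(), evalue = double(), score = double()))
  }
  stopifnot(all(c("gene_id", "profile", "source", "aa_start", "aa_end") %in% names(plan)),
            all(plan$aa_start <= plan$aa_end))
  with_seed(seed, {
    ev <- 10^runif(nrow(plan), log10(evalue_range[1]), log10(evalue_range[2]))
    if ("evalue" %in% names(plan)) ev <- ifelse(is.na(plan$evalue), ev, plan$evalue)
    tibble(gene_id = plan$gene_id, profile = plan$profile,
           source = plan$source,
           aa_start = as.integer(plan$aa_start), aa_end = as.integer(plan$aa_end),
           evalue = ev,
           # crude bits-from-E-value conversion; only ordering matters here
           score = round(-log10(ev) * 2 + rnorm(nrow(plan), 0, 0.5), 1))
  })
}

#' Simulate Brownian-motion traits with a linear effect on a tree
#'
#' Draws a predictor `x` independently per tip (standard normal) and a
#' response `y = intercept + slope * x + e`, with `e` multivariate normal
#' with covariance `sigma2` times the shared-branch-length matrix of the
#' tree. This is the generating model under which phylogenetic generalized
#' least squares is the efficient estimator.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param slope,intercept Linear effect parameters.
#' @param sigma2 Brownian rate (variance per unit branch length); `0` gives
#'   a noise-free linear relation.
#' @param seed Integer seed.
#' @return A tibble with columns `taxon`, `x`, `y`.
#' @examples
#' tr <- ape::rcoal(8)
#' simulate_brownian_traits(tr, slope = 2, intercept = 1, sigma2 = 1, seed = 1)
#' @export
simulate_brownian_traits <- function(tree, slope, intercept, sigma2,
                                     seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    abort("Tree must have non-negative branch lengths.")
  V <- ape::vcv(tree)
  if (all(diag(V) == 0)) abort("Zero-length tree: no variance to simulate.")
  n <- nrow(V)
  with_seed(seed, {
    x <- rnorm(n)
    e <- if (sigma2 > 0) {
      as.vector(t(chol(sigma2 * V)) %*% rnorm(n))
    } else rep(0, n)
    tibble(taxon = rownames(V), x = x, y = intercept + slope * x + e)
  })
}
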