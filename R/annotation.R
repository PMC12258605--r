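# Resolution of competing domain annotations, canonical category mapping,
# NLR candidate calling and architecture classification.
#
# Domain hits come from three profile collections ("sources") with a fixed
# priority order: curated fungal-NLR N-terminal profiles (wojciechowski) >
# order-specific profiles (sordariales_specific) > Pfam-A (pfam_a). When
# hits from the same source compete for the same region, the best hit is
# kept only if its E-value beats the *square* of every competitor's
# E-value -- a deliberately conservative margin; otherwise the region is
# reported as undetermined (NB competitions) or all predictions are kept
# (other domain classes).

SOURCE_PRIORITY <- c(wojciechowski = 1, sordariales_specific = 2, pfam_a = 3)

CANONICAL_NTERM <- c("HeLo-like", "sesB-like", "Goodbye-like", "HET-like",
                     "PNP_UDP_1", "RelA_SpoT", "Patatin", "amyloid")
CANONICAL_CTERM <- c("Ankyrin", "TPR", "WD40", "HEAT")

#' Default profile-to-category map
#'
#' Maps profile names to canonical categories and category classes.
#' Canonical N-terminal categories are HeLo-like, sesB-like, Goodbye-like,
#' HET-like, PNP_UDP_1, RelA_SpoT, Patatin and amyloid; canonical
#' C-terminal categories are Ankyrin, TPR, WD40 and HEAT. `sesA` is merged
#' into HeLo-like and `NAD1` into Goodbye-like (the annotated sets overlap
#' extensively), and all amyloid-motif profiles map to the single
#' `amyloid` category.
#'
#' @return A tibble with columns `profile`, `category`, `class` (one of
#'   `"nterm"`, `"NB"`, `"cterm"`).
#' @export
default_category_map <- function() {
  tibble::tribble(
    ~profile,       ~category,      ~class,
    "NACHT",        "NACHT",        "NB",
    "NB-ARC",       "NB-ARC",       "NB",
    "AAA",          "AAA",          "NB",
    "Ankyrin",      "Ankyrin",      "cterm",
    "Ank_2",        "Ankyrin",      "cterm",
    "Ank_4",        "Ankyrin",      "cterm",
    "TPR",          "TPR",          "cterm",
    "TPR_1",        "TPR",          "cterm",
    "TPR_2",        "TPR",          "cterm",
    "WD40",         "WD40",         "cterm",
    "HEAT",         "HEAT",         "cterm",
    "HEAT_2",       "HEAT",         "cterm",
    "HeLo",         "HeLo-like",    "nterm",
    "HeLo-like",    "HeLo-like",    "nterm",
    "sesA",         "HeLo-like",    "nterm",
    "sesB",         "sesB-like",    "nterm",
    "sesB-like",    "sesB-like",    "nterm",
    "Goodbye",      "Goodbye-like", "nterm",
    "Goodbye-like", "Goodbye-like", "nterm",
    "NAD1",         "Goodbye-like", "nterm",
    "HET",          "HET-like",     "nterm",
    "HET-like",     "HET-like",     "nterm",
    "PNP_UDP_1",    "PNP_UDP_1",    "nterm",
    "RelA_SpoT",    "RelA_SpoT",    "nterm",
    "Patatin",      "Patatin",      "nterm",
    "HRAM",         "amyloid",      "nterm",
    "sigma_NLR",    "amyloid",      "nterm",
    "PP_amyloid",   "amyloid",      "nterm"
  )
}

#' Map a profile name to its canonical category
#'
#' Unknown profiles are returned as non-canonical, labelled with the
#' profile's own name and class `"noncanonical"`.
#'
#' @param profile Character vector of profile names.
#' @param map A category map, as [default_category_map()].
#' @return A tibble with columns `profile`, `category`, `class`.
#' @examples
#' categorize_domain(c("sesA", "NAD1", "Lipocalin_5"))
#' @export
categorize_domain <- function(profile, map = default_category_map()) {
  out <- left_join(tibble(profile = profile), as_tibble(map), by = "profile")
  mutate(out,
         category = ifelse(is.na(.data$category), .data$profile, .data$category),
         class = ifelse(is.na(.data$class), "noncanonical", .data$class))
}

#' Resolve competing domain hits
#'
#' Hits on the same gene whose amino-acid intervals overlap by at least
#' `overlap_fraction` of the shorter interval compete (connected components
#' of the pairwise overlap graph form one competition each). Competitions
#' are settled in two steps: hits from the highest-priority source present
#' win outright; among same-source survivors the lowest-E-value hit is
#' retained iff its E-value is strictly lower than the squared E-value of
#' every competitor. Failing that, an NB competition yields a single call
#' with `status = "undetermined"` (an NB domain is present but untyped),
#' while for other classes all predictions are kept with
#' `status = "multiple"`. E-values of exactly zero are floored at 1e-300
#' before squaring.
#'
#' @param hits A domain-hit tibble (`gene_id`, `profile`, `source`,
#'   `aa_start`, `aa_end`, `evalue`, ...).
#' @param overlap_fraction Fraction of the shorter interval that must be
#'   covered for two hits to compete, in (0, 1].
#' @param map Category map used to attach `category` and `class`.
#' @return A domain-call tibble: `gene_id`, `profile`, `category`, `class`,
#'   `aa_start`, `aa_end`, `evalue`, `source`, `status` (one of
#'   `"resolved"`, `"undetermined"`, `"multiple"`). Output order is
#'   independent of input row order.
#' @export
resolve_competing_hits <- function(hits, overlap_fraction = 0.5,
                                   map = default_category_map()) {
  stopifnot(overlap_fraction > 0, overlap_fraction <= 1)
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), profile = character(),
                  category = character(), class = character(),
                  aa_start = integer(), aa_end = integer(),
                  evalue = double(), source = character(), status = character()))
  }
  stopifnot(all(hits$aa_start <= hits$aa_end), all(hits$evalue > 0))
  cat_info <- categorize_domain(hits$profile, map)
  hits$category <- cat_info$category
  hits$class <- cat_info$class
  # Canonical row order makes the result independent of input permutation.
  hits <- arrange(hits, .data$gene_id, .data$aa_start, .data$aa_end,
                  .data$profile, .data$source, .data$evalue)

  resolve_gene <- function(g) {
    n <- nrow(g)
    if (n == 1) return(mutate(g, status = "resolved"))
    # Competition graph: overlap >= fraction of the shorter interval.
    ov <- outer(seq_len(n), seq_len(n), function(i, j) {
      len_i <- g$aa_end[i] - g$aa_start[i] + 1
      len_j <- g$aa_end[j] - g$aa_start[j] + 1
      o <- interval_overlap(g$aa_start[i], g$aa_end[i], g$aa_start[j], g$aa_end[j])
      o >= overlap_fraction * pmin(len_i, len_j)
    })
    comp <- connected_components(ov)
    purrr::map_dfr(unique(comp), function(cc) {
      grp <- g[comp == cc, , drop = FALSE]
      if (nrow(grp) == 1) return(mutate(grp, status = "resolved"))
      pri <- SOURCE_PRIORITY[grp$source]
      pri[is.na(pri)] <- max(SOURCE_PRIORITY) + 1
      grp <- grp[pri == min(pri), , drop = FALSE]
      if (nrow(grp) == 1) return(mutate(grp, status = "resolved"))
      ev <- pmax(grp$evalue, 1e-300)
      best <- which.min(ev)
      if (all(ev[best] < ev[-best]^2)) {
        return(mutate(grp[best, , drop = FALSE], status = "resolved"))
      }
      if (all(grp$class == "NB")) {
        out <- grp[best, , drop = FALSE]
        out$category <- "NB-undetermined"
        mutate(out, status = "undetermined")
      } else {
        mutate(grp, status = "multiple")
      }
    })
  }
  hits |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map_dfr(resolve_gene) |>
    arrange(.data$gene_id, .data$aa_start, .data$aa_end, .data$profile)
}

# Connected components of a logical adjacency matrix (tiny n: label
# propagation is plenty).
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      m <- min(comp[c(i, nb)])
      if (any(comp[c(i, nb)] != m)) {
        comp[c(i, nb)] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Call candidate NLR genes
#'
#' A candidate NLR encodes at least one NB-class call and at least one
#' canonical C-terminal call (Ankyrin, TPR, WD40 or HEAT) located
#' C-terminal of the NB (call midpoint beyond the NB region midpoint), and
#' its gene is longer than 1 kb (strict).
#'
#' @param calls A domain-call tibble from [resolve_competing_hits()].
#' @param gene_lengths A data frame with columns `gene_id` and
#'   `gene_length` (bp), or a named numeric vector.
#' @param min_gene_length_bp Length filter; genes must be strictly longer.
#' @return Character vector of candidate gene ids (sorted).
#' @export
call_nlr_candidates <- function(calls, gene_lengths,
                                min_gene_length_bp = 1000) {
  calls <- as_tibble(calls)
  if (!is.data.frame(gene_lengths)) {
    gene_lengths <- tibble(gene_id = names(gene_lengths),
                           gene_length = as.numeric(gene_lengths))
  }
  gene_lengths <- as_tibble(gene_lengths)
  missing <- setdiff(unique(calls$gene_id), gene_lengths$gene_id)
  if (length(missing) > 0) {
    abort(paste0("No gene length for: ", paste(missing, collapse = ", ")))
  }
  keep_status <- c("resolved", "undetermined", "multiple")
  cand <- calls |>
    filter(.data$status %in% keep_status) |>
    group_by(.data$gene_id) |>
    summarise(has_nb = any(.data$class == "NB"),
              nb_mid = if (any(.data$class == "NB")) {
                mean(c(.data$aa_start[.data$class == "NB"][1],
                       .data$aa_end[.data$class == "NB"][1]))
              } else NA_real_,
              has_cterm = any(.data$class == "cterm" &
                                .data$category %in% CANONICAL_CTERM &
                                (.data$aa_start + .data$aa_end) / 2 >
                                  mean(c(.data$aa_start[.data$class == "NB"][1],
                                         .data$aa_end[.data$class == "NB"][1]))),
              .groups = "drop") |>
    filter(.data$has_nb, .data$has_cterm) |>
    left_join(gene_lengths, by = "gene_id") |>
    filter(.data$gene_length > min_gene_length_bp)
  sort(cand$gene_id)
}

#' Classify the domain architecture of an NLR
#'
#' Calls flanking the NB region are assigned to the N- or C-terminal side
#' by their midpoint relative to the NB region midpoint. Each side is then
#' labelled: `canonical` (exactly one canonical category), `mixed` (two or
#' more distinct canonical categories), `noncanonical` (no canonical but at
#' least one non-canonical call), `missing` (no call and the flanking
#' region is shorter than 20 aa on the N side / 50 aa on the C side, i.e. a
#' truncated NLR), or `undetermined` (no call on a side long enough to hold
#' one). The combined architecture class is `tripartite` when both sides
#' are canonical; `mixed` when either side is mixed; then
#' `missing-both`/`missing-N`/`missing-C`; then `non-canonical`; else
#' `undetermined`.
#'
#' @param calls Domain-call tibble for a single gene (must contain one
#'   NB-class call; `undetermined` NB calls count).
#' @param protein_length Protein length in aa.
#' @param nterm_min_aa,cterm_min_aa Truncation thresholds for the two ends.
#' @return A one-row tibble: `architecture_class`, `nterm_category`,
#'   `cterm_category`, `nterm_side`, `cterm_side`, `noncanonical_domains`
#'   (list column).
#' @export
classify_architecture <- function(calls, protein_length,
                                  nterm_min_aa = 20, cterm_min_aa = 50) {
  calls <- filter(as_tibble(calls),
                  .data$status %in% c("resolved", "undetermined", "multiple"))
  nb <- filter(calls, .data$class == "NB")
  if (nrow(nb) == 0) abort("classify_architecture() needs an NB-class call.")
  nb <- nb[1, ]
  nb_mid <- (nb$aa_start + nb$aa_end) / 2
  flank <- filter(calls, .data$class != "NB")
  flank <- mutate(flank, side = ifelse((.data$aa_start + .data$aa_end) / 2 < nb_mid,
                                       "N", "C"))

  side_label <- function(side_calls, canonical_set, region_len, min_aa) {
    canon <- unique(side_calls$category[side_calls$category %in% canonical_set])
    noncanon <- unique(side_calls$category[side_calls$class == "noncanonical"])
    if (length(canon) >= 2) return(list(label = "mixed", category = paste(sort(canon), collapse = "+")))
    if (length(canon) == 1) return(list(label = "canonical", category = canon))
    if (length(noncanon) >= 1) return(list(label = "noncanonical", category = noncanon[1]))
    if (region_len < min_aa) return(list(label = "missing", category = NA_character_))
    list(label = "undetermined", category = NA_character_)
  }
  nside <- side_label(filter(flank, .data$side == "N"), CANONICAL_NTERM,
                      nb$aa_start - 1, nterm_min_aa)
  cside <- side_label(filter(flank, .data$side == "C"), CANONICAL_CTERM,
                      protein_length - nb$aa_end, cterm_min_aa)

  labels <- c(nside$label, cside$label)
  arch <- if (all(labels == "canonical")) "tripartite"
  else if (any(labels == "mixed")) "mixed"
  else if (all(labels == "missing")) "missing-both"
  else if (nside$label == "missing") "missing-N"
  else if (cside$label == "missing") "missing-C"
  else if (any(labels == "noncanonical")) "non-canonical"
  else "undetermined"

  noncanon <- unique(flank$category[flank$class == "noncanonical"])
  tibble(architecture_class = arch,
         nterm_category = nside$category, cterm_category = cside$category,
         nterm_side = nside$label, cterm_side = cside$label,
         noncanonical_domains = list(noncanon))
}

#' Filter genome-alignment hits for NLR correction
#'
#' Retains scored alignment hits that (i) reach `min_score`, (ii) overlap
#' at least one NB-domain interval by at least one base, and (iii) carry
#' neither a stop-codon nor a frameshift flag.
#'
#' @param hits A tibble with columns `start`, `end`, `score`, `stop_codon`,
#'   `frameshift` (logical flags).
#' @param nb_intervals A data frame of NB intervals with columns `start`,
#'   `end`.
#' @param min_score Minimum alignment score (default 200).
#' @return The retained rows of `hits`.
#' @export
filter_alignment_hits <- function(hits, nb_intervals, min_score = 200) {
  hits <- as_tibble(hits)
  nb_intervals <- as_tibble(nb_intervals)
  if (nrow(hits) == 0) return(hits)
  overlaps_nb <- vapply(seq_len(nrow(hits)), function(i) {
    any(interval_overlap(hits$start[i], hits$end[i],
                         nb_intervals$start, nb_intervals$end) >= 1)
  }, logical(1))
  filter(hits, .data$score >= min_score, overlaps_nb,
         !.data$stop_codon, !.data$frameshift)
}
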