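# Degenerate consensus motifs and NB-domain typing.
#
# Fungal NLR nucleotide-binding (NB) domains come in two lineages, NACHT and
# NB-ARC, distinguishable by their Walker B motif: in NACHT domains the
# first aspartate is followed by a small residue (G/A/S) with a second
# acidic residue three positions downstream (consensus hhhhD[GAS]hDE),
# whereas in NB-ARC domains the first aspartate is directly followed by
# another acidic residue. NACHT domains further split into the rare
# NAIP-like (N-NACHT) and the common TLP1-like (T-NACHT) subtypes: N-NACHT
# carries the consensus FhHxxhQE[YF]hxA in the HETHS (helical third) region
# C-terminal of the Walker B.

# Residues treated as hydrophobic for the `h` wildcard. Configurable in
# every matcher; this default follows the P-loop NTPase literature.
DEFAULT_HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Consensus motifs used throughout the package.
MOTIF_WALKER_A      <- "GxxxxGK[ST]"
MOTIF_WALKER_B_NACHT <- "hhhhD[GAS]hDE"
MOTIF_WALKER_B_NBARC <- "hhhhD[DE]"
MOTIF_HETHS_NAIP    <- "FhHxxhQE[YF]hxA"

#' Parse a degenerate protein motif
#'
#' Motif syntax: a literal residue matches itself; `h` matches the
#' hydrophobic set; `x` matches any residue; `[ABC]` matches any residue in
#' the brackets. `X` in a scanned sequence matches only `x`.
#'
#' @param motif Motif string, e.g. `"hhhhD[GAS]hDE"`.
#' @param hydrophobic Character vector of residues the `h` wildcard matches.
#' @return A list with one character vector of admissible residues per
#'   position, or the string `"*"` for an any-residue position.
#' @keywords internal
parse_motif <- function(motif, hydrophobic = DEFAULT_HYDROPHOBIC) {
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) == 0) {
    abort("`motif` must be a non-empty motif string.")
  }
  chars <- strsplit(motif, "")[[1]]
  out <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j) || j == i + 1) abort("Malformed residue class in motif.")
      out[[length(out) + 1]] <- chars[(i + 1):(j - 1)]
      i <- j + 1
    } else if (ch == "h") {
      out[[length(out) + 1]] <- hydrophobic
      i <- i + 1
    } else if (ch == "x") {
      out[[length(out) + 1]] <- "*"
      i <- i + 1
    } else {
      out[[length(out) + 1]] <- ch
      i <- i + 1
    }
  }
  out
}

#' Find all matches of a degenerate motif in a protein sequence
#'
#' Scans every window of the sequence against a degenerate consensus motif
#' and returns all matching start positions, left to right. `x` positions
#' match any residue (including the ambiguity code `X`); all other motif
#' positions require one of their admissible residues, so `X` in the
#' sequence never satisfies them.
#'
#' @param seq A single protein sequence (character scalar, one-letter code).
#' @param motif Motif string; see [parse_motif()] for the syntax.
#' @param hydrophobic Residues matched by the `h` wildcard.
#' @return A tibble with columns `aa_start` (1-based), `matched_substring`
#'   and `motif_id`; zero rows when there is no match.
#' @examples
#' match_motif("MVLIFDGLDEK", "hhhhD[GAS]hDE")
#' @export
match_motif <- function(seq, motif, hydrophobic = DEFAULT_HYDROPHOBIC) {
  stopifnot(is.character(seq), length(seq) == 1)
  pat <- parse_motif(motif, hydrophobic)
  m <- length(pat)
  n <- nchar(seq)
  starts <- integer(0)
  if (n >= m) {
    chars <- strsplit(toupper(seq), "")[[1]]
    ok_pos <- lapply(pat, function(p) {
      if (identical(p, "*")) rep(TRUE, n) else chars %in% p
    })
    cand <- rep(TRUE, n - m + 1)
    for (k in seq_len(m)) {
      cand <- cand & ok_pos[[k]][k:(n - m + k)]
    }
    starts <- which(cand)
  }
  tibble(
    aa_start = as.integer(starts),
    matched_substring = if (length(starts)) substring(seq, starts, starts + m - 1) else character(0),
    motif_id = rep(motif, length(starts))
  )
}

#' Classify a Walker B motif as NACHT or NB-ARC
#'
#' NACHT takes precedence: a sequence matching the NACHT consensus
#' `hhhhD[GAS]hDE` is NACHT even if it also contains an NB-ARC-style
#' Walker B elsewhere. NB-ARC is recognised by the first aspartate being
#' directly followed by an acidic residue (`hhhhD[DE]`). The leftmost match
#' of the winning consensus is reported.
#'
#' @param seq A single protein sequence.
#' @param hydrophobic Residues matched by the `h` wildcard.
#' @return A one-row tibble with columns `walkerB_type` (`"NACHT"`,
#'   `"NB-ARC"` or `"neither"`), `aa_start` and `matched_substring` (NA
#'   when there is no match).
#' @examples
#' classify_walker_b("AAVLIFDGLDEKAA")$walkerB_type
#' @export
classify_walker_b <- function(seq, hydrophobic = DEFAULT_HYDROPHOBIC) {
  nacht <- match_motif(seq, MOTIF_WALKER_B_NACHT, hydrophobic)
  if (nrow(nacht) > 0) {
    return(tibble(walkerB_type = "NACHT",
                  aa_start = nacht$aa_start[1],
                  matched_substring = nacht$matched_substring[1]))
  }
  nbarc <- match_motif(seq, MOTIF_WALKER_B_NBARC, hydrophobic)
  if (nrow(nbarc) > 0) {
    return(tibble(walkerB_type = "NB-ARC",
                  aa_start = nbarc$aa_start[1],
                  matched_substring = nbarc$matched_substring[1]))
  }
  tibble(walkerB_type = "neither",
         aa_start = NA_integer_, matched_substring = NA_character_)
}

#' Classify a NACHT domain as NAIP-like (N-NACHT) or TLP1-like (T-NACHT)
#'
#' A NACHT sequence is N-NACHT when the NAIP-like HETHS consensus
#' `FhHxxhQE[YF]hxA` matches downstream of the Walker B match (the HETHS
#' region lies C-terminal of the core P-loop domain); otherwise it is
#' T-NACHT.
#'
#' @param seq A single protein sequence already classified as NACHT.
#' @param walkerB_start 1-based start of the Walker B match in `seq`.
#' @param hydrophobic Residues matched by the `h` wildcard.
#' @return A one-row tibble with `nacht_subtype` (`"N-NACHT"` or
#'   `"T-NACHT"`) and `heths_start` (NA for T-NACHT).
#' @export
classify_nacht_subtype <- function(seq, walkerB_start,
                                   hydrophobic = DEFAULT_HYDROPHOBIC) {
  stopifnot(walkerB_start >= 1, walkerB_start <= nchar(seq))
  wb_len <- nchar(MOTIF_WALKER_B_NACHT) - 4L  # "hhhhD[GAS]hDE" spans 9 aa
  window_from <- walkerB_start + wb_len
  if (window_from > nchar(seq)) {
    return(tibble(nacht_subtype = "T-NACHT", heths_start = NA_integer_))
  }
  downstream <- substring(seq, window_from, nchar(seq))
  m <- match_motif(downstream, MOTIF_HETHS_NAIP, hydrophobic)
  if (nrow(m) > 0) {
    tibble(nacht_subtype = "N-NACHT",
           heths_start = as.integer(m$aa_start[1] + window_from - 1L))
  } else {
    tibble(nacht_subtype = "T-NACHT", heths_start = NA_integer_)
  }
}

#' Type an NB domain as T-NACHT, N-NACHT, NB-ARC or undetermined
#'
#' Composes [classify_walker_b()] and [classify_nacht_subtype()]: no Walker
#' B match of either consensus gives `"undetermined"`; an NB-ARC Walker B
#' gives `"NB-ARC"`; a NACHT Walker B is refined into N-NACHT or T-NACHT by
#' the NAIP-like HETHS motif downstream.
#'
#' @param seq One protein sequence, or a named character vector of
#'   sequences (names become `gene_id`).
#' @param hydrophobic Residues matched by the `h` wildcard.
#' @return A tibble with one row per sequence: `gene_id` (if names were
#'   given), `nb_type`, `walkerB_start`, `heths_start`.
#' @examples
#' type_nb_domain(c(g1 = "AAVLIFDGLDEKAAFLHLTYQEYFAAGG"))
#' @export
type_nb_domain <- function(seq, hydrophobic = DEFAULT_HYDROPHOBIC) {
  one <- function(s) {
    wb <- classify_walker_b(s, hydrophobic)
    if (wb$walkerB_type == "neither") {
      return(tibble(nb_type = "undetermined",
                    walkerB_start = NA_integer_, heths_start = NA_integer_))
    }
    if (wb$walkerB_type == "NB-ARC") {
      return(tibble(nb_type = "NB-ARC",
                    walkerB_start = wb$aa_start, heths_start = NA_integer_))
    }
    sub <- classify_nacht_subtype(s, wb$aa_start, hydrophobic)
    tibble(nb_type = sub$nacht_subtype,
           walkerB_start = wb$aa_start, heths_start = sub$heths_start)
  }
  out <- purrr::map_dfr(unname(seq), one)
  if (!is.null(names(seq))) out <- mutate(out, gene_id = names(seq), .before = 1)
  out
}

#' Split an NB sequence into the two fragments used for ordination
#'
#' Fragment 1 runs from the N-terminal end to the residue before the Walker
#' B start; fragment 2 from the Walker B start to the C-terminal end, so
#' their concatenation reconstructs the input.
#'
#' @param seq A single protein sequence.
#' @param walkerB_start 1-based Walker B start; must satisfy
#'   `1 < walkerB_start <= nchar(seq)` (both fragments non-empty).
#' @return A list with elements `fragment1` and `fragment2`.
#' @examples
#' split_nb_fragments("ABCDEFGHIJ", 4)
#' @export
split_nb_fragments <- function(seq, walkerB_start) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  if (is.na(walkerB_start) || walkerB_start <= 1 || walkerB_start > n) {
    abort("`walkerB_start` must lie in (1, nchar(seq)]: both fragments must be non-empty.")
  }
  list(fragment1 = substring(seq, 1, walkerB_start - 1),
       fragment2 = substring(seq, walkerB_start, n))
}
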