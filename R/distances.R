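# Alignment-free sequence distances and the BLOSUM62 pairwise distance
# index.
#
# Two alignment-free metrics are provided for comparing NB-domain
# fragments without a multiple alignment: a normalized k-mer set distance
# (Google-style, default k = 3) and a normalized Lempel-Ziv complexity
# distance (Otu-Sayood form). Both feed a principal coordinates analysis
# whose qualitative structure -- separation of NB-ARC from NACHT fragments
# on the first axis -- is the assertable output.

#' Distinct k-mers of a sequence
#'
#' @param seq A single sequence (character scalar).
#' @param k Word size (>= 1).
#' @return Character vector of distinct length-`k` substrings; empty when
#'   `k > nchar(seq)`.
#' @examples
#' kmer_set("ABAB", 2)
#' @export
kmer_set <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1, k >= 1)
  n <- nchar(seq)
  if (k > n) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Normalized Google distance between k-mer sets
#'
#' With `A` and `B` the k-mer sets of the two sequences,
#' `d = (|A| + |B| - 2|A∩B|) / (|A| + |B| - |A∩B|)`: 0 for identical sets,
#' 1 for disjoint sets.
#'
#' @param s1,s2 Sequences (character scalars), each of length >= `k`.
#' @param k Word size (default 3).
#' @return A number in \[0, 1\].
#' @examples
#' google_distance("ABCD", "BCDE", k = 2)
#' @export
google_distance <- function(s1, s2, k = 3) {
  if (nchar(s1) < k || nchar(s2) < k) {
    abort("Both sequences must be at least `k` characters long.")
  }
  a <- kmer_set(s1, k)
  b <- kmer_set(s2, k)
  inter <- length(intersect(a, b))
  (length(a) + length(b) - 2 * inter) / (length(a) + length(b) - inter)
}

#' Lempel-Ziv (1976) complexity of a sequence
#'
#' Number of components in the exhaustive-history parsing: scanning left to
#' right, each new component extends while it can be copied from the
#' already-seen part of the sequence and closes on the first position at
#' which it cannot.
#'
#' @param seq A single non-empty sequence.
#' @return Integer component count.
#' @examples
#' lz_complexity("aaaa")  # parses as a | aaa
#' @export
lz_complexity <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  if (n == 0) abort("`seq` must be non-empty.")
  # A component starting at p extends while s[p..q] can be copied from the
  # already-produced prefix s[1..q-1] (self-overlapping copies allowed) and
  # closes on the first q at which it cannot. Reproducibility is monotone
  # in q, so the closing position is found by binary search.
  reproducible <- function(p, q) {
    # is s[p..q] a substring of s[1..q-1]?
    if (q - p + 1 > q - 1) return(FALSE)
    grepl(substring(seq, p, q), substring(seq, 1, q - 1), fixed = TRUE)
  }
  c_count <- 0L
  p <- 1L
  while (p <= n) {
    c_count <- c_count + 1L
    if (!reproducible(p, p)) { p <- p + 1L; next }
    # find largest q with s[p..q] reproducible; component ends at q+1 (or n)
    lo <- p; hi <- n
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (reproducible(p, mid)) lo <- mid else hi <- mid - 1L
    }
    p <- min(lo + 1L, n) + 1L
  }
  c_count
}

#' Normalized Lempel-Ziv complexity distance
#'
#' Otu-Sayood form:
#' `d = max(C(s1 s2) - C(s1), C(s2 s1) - C(s2)) / max(C(s1), C(s2))`,
#' symmetric and non-negative by construction.
#'
#' @param s1,s2 Non-empty sequences.
#' @return A non-negative number.
#' @export
lz_distance <- function(s1, s2) {
  c1 <- lz_complexity(s1)
  c2 <- lz_complexity(s2)
  c12 <- lz_complexity(paste0(s1, s2))
  c21 <- lz_complexity(paste0(s2, s1))
  max(c12 - c1, c21 - c2) / max(c1, c2)
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' BLOSUM62 distance index between two aligned sequences
#'
#' Over the columns where neither sequence has a gap (`-`),
#' `d = 1 - S12 / max(S11, S22)`, with `Sxy` the summed BLOSUM62 scores of
#' the column pairs between sequences x and y. Identical sequences give 0.
#'
#' @param s1,s2 Equal-length gapped protein sequences.
#' @return The distance index.
#' @examples
#' blosum62_distance("AR", "AK")  # 1 - 6/9
#' @export
blosum62_distance <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) abort("Aligned sequences must have equal length.")
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) abort("No gap-free columns shared by the two sequences.")
  a <- a[keep]; b <- b[keep]
  B <- blosum62_matrix()
  s11 <- sum(B[cbind(a, a)])
  s22 <- sum(B[cbind(b, b)])
  s12 <- sum(B[cbind(a, b)])
  1 - s12 / max(s11, s22)
}

#' Pairwise distance matrix over labelled sequences
#'
#' @param seqs Named character vector of sequences (>= 2), or a tibble with
#'   columns `gene_id` and `sequence`.
#' @param metric `"google"`, `"lz"` or `"blosum62"` (the latter requires
#'   pre-aligned equal-length sequences).
#' @param k Word size for the Google distance.
#' @return A symmetric numeric matrix with zero diagonal and the sequence
#'   names as dimnames.
#' @export
pairwise_distance_matrix <- function(seqs, metric = c("google", "lz", "blosum62"),
                                     k = 3) {
  metric <- match.arg(metric)
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$gene_id)
  if (length(seqs) < 2) abort("Need at least two sequences.")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  f <- switch(metric,
              google = function(a, b) google_distance(a, b, k = k),
              lz = lz_distance,
              blosum62 = blosum62_distance)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- tryCatch(f(seqs[[i]], seqs[[j]]), error = function(e) {
        abort(sprintf("Distance failed for pair (%s, %s): %s",
                      names(seqs)[i], names(seqs)[j], conditionMessage(e)))
      })
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Write / read a labelled distance matrix as TSV
#'
#' @param dm Symmetric matrix with dimnames.
#' @param path File path.
#' @return `path` invisibly / the matrix.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- as_tibble(dm, rownames = "label")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$label
  m
}
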