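# Independent brute-force oracles used to validate the package
# implementations. Each is written from the definition, by a different
# route than the implementation it checks.

# Expand a degenerate motif into every literal string it admits.
expand_motif_literals <- function(motif, hydrophobic) {
  chars <- strsplit(motif, "")[[1]]
  sets <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      sets[[length(sets) + 1]] <- chars[(i + 1):(j - 1)]
      i <- j + 1
    } else if (ch == "h") {
      sets[[length(sets) + 1]] <- hydrophobic
      i <- i + 1
    } else if (ch == "x") {
      sets[[length(sets) + 1]] <- NA  # wildcard marker
      i <- i + 1
    } else {
      sets[[length(sets) + 1]] <- ch
      i <- i + 1
    }
  }
  sets
}

# Oracle motif matcher: compare every window against every literal
# expansion (wildcards compared positionally).
oracle_match_positions <- function(seq, motif, hydrophobic, alphabet) {
  sets <- expand_motif_literals(motif, hydrophobic)
  sets <- lapply(sets, function(s) if (anyNA(s)) alphabet else s)
  literals <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  literals <- apply(literals, 1, paste, collapse = "")
  m <- length(sets)
  n <- nchar(seq)
  if (n < m) return(integer(0))
  windows <- substring(seq, 1:(n - m + 1), m:n)
  which(windows %in% literals)
}

# Oracle LZ76 component count: literal definition with an explicit search
# over all copy start positions (no regex machinery).
oracle_lz_complexity <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  count <- 0L
  p <- 1L
  while (p <= n) {
    count <- count + 1L
    q <- p
    repeat {
      # can s[p..q] be copied from s[1..q-1]?
      len <- q - p + 1L
      found <- FALSE
      if (q - 1L >= len) {
        for (st in 1:(q - len)) {
          if (all(s[st:(st + len - 1L)] == s[p:q])) { found <- TRUE; break }
        }
      }
      if (!found || q == n) break
      q <- q + 1L
    }
    # component ends at first non-reproducible position (or sequence end)
    p <- q + 1L
  }
  count
}

# Oracle cluster detector: enumerate every contiguous run of NLRs, keep
# runs whose consecutive pairs all satisfy the thresholds, then keep only
# maximal runs.
oracle_clusters <- function(genes, max_gap_bp, max_intervening) {
  genes <- genes[order(genes$contig, genes$start), ]
  out <- list()
  for (ctg in unique(genes$contig)) {
    g <- genes[genes$contig == ctg, ]
    idx <- which(g$is_nlr)
    if (length(idx) < 2) next
    pair_ok <- function(a, b) {  # consecutive NLR indices into g
      gap <- max(0, g$start[b] - g$end[a] - 1)
      gap <= max_gap_bp && (b - a - 1) <= max_intervening
    }
    runs <- list()
    for (i in seq_along(idx)) {
      for (j in seq_along(idx)) {
        if (j <= i) next
        ok <- TRUE
        for (k in i:(j - 1)) {
          if (!pair_ok(idx[k], idx[k + 1])) { ok <- FALSE; break }
        }
        if (ok) runs[[length(runs) + 1]] <- i:j
      }
    }
    if (length(runs) == 0) next
    maximal <- Filter(function(r) {
      !any(vapply(runs, function(r2) length(r2) > length(r) && all(r %in% r2),
                  logical(1)))
    }, runs)
    for (r in maximal) {
      out[[length(out) + 1]] <- g$gene_id[idx[r]]
    }
  }
  out
}

# Oracle plateau scan: vectorised window test over all length-3 windows.
oracle_plateau <- function(inflation, count) {
  k <- length(count)
  hit <- which(count[1:(k - 2)] == count[2:(k - 1)] &
                 count[1:(k - 2)] == count[3:k])
  if (length(hit) == 0) NA_real_ else inflation[hit[1]]
}

# Closed-form OLS for y ~ x.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# A random gene table (possibly degenerate) for property tests.
random_gene_table <- function(n_genes, nlr_prob = 0.3, contigs = 1) {
  ctg <- sort(sample(seq_len(contigs), n_genes, replace = TRUE))
  len <- sample(300:3000, n_genes, replace = TRUE)
  gap <- sample(c(0:5000, 30000:60000), n_genes, replace = TRUE)
  start <- unlist(tapply(seq_len(n_genes), ctg, function(ii) {
    cumsum(gap[ii]) + cumsum(c(0, head(len[ii], -1)))
  }))
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    contig = sprintf("ctg%d", ctg),
    start = as.integer(start),
    end = as.integer(start + len - 1),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    is_nlr = runif(n_genes) < nlr_prob
  )
}
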