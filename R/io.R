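# Readers and writers for the tabular and sequence formats the pipeline
# consumes: HMMER3 per-domain tables (domtblout), FASTA, GFF3 gene tables,
# Newick trees and TSV trait tables. Sequence and annotation formats go
# through Biostrings / rtracklayer / ape; the domtblout dialect has no
# installed parser, so it is parsed here (fixed whitespace-separated
# column order, `#` comment lines).

#' Read a HMMER3 per-domain hit table (domtblout)
#'
#' Parses the whitespace-separated `--domtblout` dialect of `hmmsearch`:
#' one row per domain, `#` lines ignored. The per-domain independent
#' E-value (column 13) and domain bit score (column 14) are used, together
#' with the envelope coordinates (columns 20-21). Row order is preserved.
#'
#' @param path File path.
#' @param source Label for the profile collection the hits come from
#'   (`"wojciechowski"`, `"sordariales_specific"` or `"pfam_a"`).
#' @return A domain-hit tibble: `gene_id`, `profile`, `source`,
#'   `aa_start`, `aa_end`, `evalue`, `score`.
#' @export
read_domtblout <- function(path, source = "pfam_a") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0) {
    return(tibble(gene_id = character(), profile = character(),
                  source = character(), aa_start = integer(),
                  aa_end = integer(), evalue = double(), score = double()))
  }
  parsed <- purrr::map(rows, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22) {
      abort(sprintf("Malformed domtblout row at line %d: expected >= 22 fields, got %d.",
                    i, length(f)))
    }
    ev <- suppressWarnings(as.numeric(f[13]))
    sc <- suppressWarnings(as.numeric(f[14]))
    from <- suppressWarnings(as.integer(f[20]))
    to <- suppressWarnings(as.integer(f[21]))
    if (anyNA(c(ev, sc, from, to))) {
      abort(sprintf("Malformed domtblout row at line %d: non-numeric E-value, score or envelope coordinate.", i))
    }
    tibble(gene_id = f[1], profile = f[4], source = source,
           aa_start = from, aa_end = to, evalue = ev, score = sc)
  })
  bind_rows(parsed)
}

#' Write a domain-hit table in domtblout layout
#'
#' Inverse of [read_domtblout()] for synthetic hit tables: emits the
#' 23-column whitespace-separated layout with the fields this package does
#' not model set to placeholders.
#'
#' @param hits A domain-hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  hits <- as_tibble(hits)
  header <- "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    paste(hits$gene_id[i], "-", 500, hits$profile[i], "-", 300,
          format(hits$evalue[i], digits = 3), hits$score[i], 0.1,
          1, 1, format(hits$evalue[i], digits = 3),
          format(hits$evalue[i], digits = 3), hits$score[i], 0.1,
          1, 100, hits$aa_start[i], hits$aa_end[i],
          hits$aa_start[i], hits$aa_end[i], 0.95, "-")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of protein sequences, or a tibble
#'   with columns `gene_id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$gene_id)
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a gene table as GFF3
#'
#' One `gene` feature per row, 1-based inclusive coordinates, `ID=`
#' attribute from `gene_id`; NLR-flagged genes carry `Note=NLR`.
#'
#' @param genes A gene table (`gene_id`, `contig`, `start`, `end`,
#'   `strand`, `is_nlr`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, path) {
  genes <- as_tibble(genes)
  attrs <- paste0("ID=", genes$gene_id,
                  ifelse(genes$is_nlr, ";Note=NLR", ""))
  lines <- paste(genes$contig, "nlrscape", "gene", genes$start, genes$end,
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a gene table from GFF3
#'
#' Reads `gene` features via rtracklayer and reconstructs the gene-table
#' layout; `is_nlr` is `TRUE` for features with a `Note` attribute equal to
#' `"NLR"` or whose `ID` is in `nlr_ids`.
#'
#' @param path GFF3 file.
#' @param nlr_ids Optional character vector of NLR gene ids.
#' @return A gene-table tibble sorted by contig and start.
#' @export
read_gene_gff3 <- function(path, nlr_ids = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gene_gff3() requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  note <- if (!is.null(gr$Note)) {
    vapply(gr$Note, function(x) any(unlist(x) == "NLR"), logical(1))
  } else rep(FALSE, length(gr))
  tibble(
    gene_id = gr$ID,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_nlr = note | (gr$ID %in% (nlr_ids %||% character(0)))
  ) |>
    arrange(.data$contig, .data$start)
}

#' Write a per-taxon trait table as TSV
#'
#' @param traits A data frame with a `taxon` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  readr::write_tsv(as_tibble(traits), path)
  invisible(path)
}

#' Read a per-taxon trait table from TSV
#'
#' @param path TSV file with a `taxon` column.
#' @return A tibble.
#' @export
read_trait_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
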