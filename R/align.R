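#' Local protein alignment statistics for one pair
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps) of two amino-acid
#' sequences, returning the score together with percent identity and the
#' fraction of each full-length protein covered by the aligned span.
#'
#' @param seq1,seq2 non-empty amino-acid strings (standard 20-letter alphabet)
#' @param params list with `substitutionMatrix` (name or matrix, default
#'   "BLOSUM62"), `gapOpening` and `gapExtension` penalties (positive costs)
#' @return list: `score`, `percent_identity` (0-100), `query_coverage` and
#'   `subject_coverage` in \[0, 1\]. A pair with no positive-scoring local
#'   alignment gets score 0 and zero coverages (match suppressed).
#' @export
align_pair <- function(seq1, seq2, params = list()) {
  check_aa(seq1); check_aa(seq2)
  sm <- params$substitutionMatrix %||% "BLOSUM62"
  if (is.character(sm)) {
    e <- new.env()
    utils::data(list = sm, package = "Biostrings", envir = e)
    sm <- get(sm, envir = e)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    type = "local", substitutionMatrix = sm,
    gapOpening = params$gapOpening %||% 10,
    gapExtension = params$gapExtension %||% 1)
  sc <- Biostrings::score(aln)
  if (!is.finite(sc) || sc <= 0) {
    return(list(score = 0, percent_identity = 0,
                query_coverage = 0, subject_coverage = 0))
  }
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  list(score = sc,
       percent_identity = Biostrings::pid(aln),
       query_coverage = (Biostrings::end(p) - Biostrings::start(p) + 1) / nchar(seq1),
       subject_coverage = (Biostrings::end(s) - Biostrings::start(s) + 1) / nchar(seq2))
}

check_aa <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("sequences must be single non-empty strings", call. = FALSE)
  }
  bad <- gsub(paste(AA_ALPHABET20, collapse = "|"), "", seq)
  if (nchar(bad) > 0L) {
    stop(sprintf("non-amino-acid symbol(s) in sequence: %s",
                 paste(unique(strsplit(bad, "")[[1]]), collapse = "")), call. = FALSE)
  }
  invisible(TRUE)
}

empty_matches <- function() {
  data.frame(query = character(0), subject = character(0), score = numeric(0),
             percent_identity = numeric(0), query_coverage = numeric(0),
             subject_coverage = numeric(0), evalue = numeric(0),
             coverage_pass = logical(0), stringsAsFactors = FALSE)
}

#' All-vs-all cross-set protein similarity
#'
#' Computes the best local match for every ordered (query, subject) pair
#' between two gene sets. Matches whose minimum of query and subject coverage
#' falls below `min_coverage` are kept but flagged `coverage_pass = FALSE`,
#' so the downstream pair accounting can report how many candidate pairs
#' failed the alignment-overlap filter.
#'
#' Two engines are available: `"align"` aligns every pair exhaustively in R
#' (quadratic; intended for small sets and tests), and `"blast"` runs NCBI
#' BLAST+ (`makeblastdb` + `blastp`) in a temporary directory and ingests the
#' tabular result through [read_blast_tabular()]. `"auto"` picks BLAST when
#' the binaries are on the PATH and the problem has more than ~100 x 100
#' sequences.
#'
#' @param genes_x,genes_y named character vectors of protein sequences
#' @param params alignment parameters (see [align_pair()]); ignored by the
#'   BLAST engine, which uses blastp defaults
#' @param min_coverage minimum alignment coverage (default 0.60)
#' @param engine "auto", "align" or "blast"
#' @param min_score suppress matches with score below this (align engine)
#' @return data.frame of directed matches: query, subject, score,
#'   percent_identity, query_coverage, subject_coverage, evalue, coverage_pass
#' @export
all_vs_all <- function(genes_x, genes_y, params = list(), min_coverage = 0.60,
                       engine = c("auto", "align", "blast"), min_score = 0) {
  engine <- match.arg(engine)
  if (length(genes_x) == 0L || length(genes_y) == 0L) {
    stop("gene sets must be non-empty", call. = FALSE)
  }
  if (is.null(names(genes_x)) || is.null(names(genes_y)) ||
      anyDuplicated(names(genes_x)) || anyDuplicated(names(genes_y))) {
    stop("gene sets must be named with unique ids", call. = FALSE)
  }
  if (engine == "auto") {
    engine <- if (has_blast() &&
                  as.double(length(genes_x)) * length(genes_y) > 10000) "blast"
              else "align"
  }
  if (engine == "blast") {
    return(blast_all_vs_all(genes_x, genes_y, min_coverage = min_coverage))
  }
  rows <- vector("list", length(genes_x) * length(genes_y))
  k <- 0L
  for (qi in seq_along(genes_x)) {
    for (si in seq_along(genes_y)) {
      a <- align_pair(genes_x[[qi]], genes_y[[si]], params)
      if (a$score <= min_score) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        query = names(genes_x)[qi], subject = names(genes_y)[si],
        score = a$score, percent_identity = a$percent_identity,
        query_coverage = a$query_coverage, subject_coverage = a$subject_coverage,
        evalue = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty_matches())
  m <- do.call(rbind, rows[seq_len(k)])
  m$coverage_pass <- pmin(m$query_coverage, m$subject_coverage) >= min_coverage
  m
}

has_blast <- function() {
  nzchar(Sys.which("blastp")) && nzchar(Sys.which("makeblastdb"))
}

# Run makeblastdb + blastp and ingest the 14-column tabular output.
blast_all_vs_all <- function(genes_x, genes_y, min_coverage = 0.60,
                             evalue = 1e-3) {
  if (!has_blast()) stop("BLAST+ binaries (blastp/makeblastdb) not on PATH", call. = FALSE)
  dir <- tempfile("blast")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fasta"); sf <- file.path(dir, "subject.fasta")
  write_protein_fasta(genes_x, qf)
  write_protein_fasta(genes_y, sf)
  db <- file.path(dir, "db")
  st <- system2("makeblastdb", c("-in", sf, "-dbtype", "prot", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("makeblastdb failed", call. = FALSE)
  outf <- file.path(dir, "hits.tsv")
  st <- system2("blastp", c("-query", qf, "-db", db, "-out", outf,
                            "-evalue", format(evalue), "-num_threads", "1",
                            "-outfmt", shQuote("6 std qlen slen")),
                stdout = FALSE, stderr = FALSE)
  if (st != 0L) stop("blastp failed", call. = FALSE)
  m <- read_blast_tabular(outf, min_coverage = min_coverage)
  m[order(m$query, m$subject), , drop = FALSE]
}

write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
}
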