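#' Read extended BLAST tabular output (14 columns)
#'
#' Parses tab-separated BLAST output in the extended dialect
#' `-outfmt "6 std qlen slen"`: the 12 standard columns (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore) followed
#' by the full query and subject lengths, which are required to compute
#' alignment coverages. When a pair has several HSPs only the highest-bitscore
#' one is kept. Coverage is alignment length over full sequence length,
#' capped at 1.
#'
#' @param path path to the tabular file
#' @param min_coverage coverage threshold used to set the `coverage_pass` flag
#' @return data.frame of directed matches (see [all_vs_all()])
#' @export
read_blast_tabular <- function(path, min_coverage = 0.60) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "slen")
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (nrow(raw) == 0L) return(empty_matches())
  if (ncol(raw) != length(cols)) {
    missing <- if (ncol(raw) == 12L) "qlen, slen" else
      paste(cols[seq(ncol(raw) + 1L, length(cols))], collapse = ", ")
    stop(sprintf(paste0("expected 14-column BLAST tabular (outfmt \"6 std qlen slen\"), ",
                        "got %d columns; missing: %s"), ncol(raw), missing),
         call. = FALSE)
  }
  names(raw) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore", "qlen", "slen")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    if (anyNA(v)) stop(sprintf("non-numeric value in column %s", cn), call. = FALSE)
    raw[[cn]] <- v
  }
  if (any(raw$qlen <= 0) || any(raw$slen <= 0)) {
    stop("qlen/slen must be positive", call. = FALSE)
  }
  # best HSP per ordered pair (max bitscore; deterministic on ties by file order)
  key <- paste(raw$qseqid, raw$sseqid, sep = "\r")
  o <- order(key, -raw$bitscore)
  raw <- raw[o, , drop = FALSE]
  raw <- raw[!duplicated(key[o]), , drop = FALSE]
  m <- data.frame(query = raw$qseqid, subject = raw$sseqid,
                  score = raw$bitscore, percent_identity = raw$pident,
                  query_coverage = pmin(1, raw$length / raw$qlen),
                  subject_coverage = pmin(1, raw$length / raw$slen),
                  evalue = raw$evalue, stringsAsFactors = FALSE)
  m$coverage_pass <- pmin(m$query_coverage, m$subject_coverage) >= min_coverage
  rownames(m) <- NULL
  m
}
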