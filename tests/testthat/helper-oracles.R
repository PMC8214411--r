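# Independent brute-force oracles and small fixture builders.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Quadratic affine-gap Smith-Waterman (Gotoh), scoring a gap of length L as
# gapOpening + L * gapExtension. Returns the optimal local score.
sw_oracle <- function(s1, s2, mat = blosum62, gap_open = 10, gap_ext = 1) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)   # best ending in match/mismatch or fresh start
  E <- matrix(-Inf, n + 1, m + 1) # gap in s2 (vertical)
  F <- matrix(-Inf, n + 1, m + 1) # gap in s1 (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - gap_open - gap_ext, E[i - 1, j] - gap_ext)
      F[i, j] <- max(H[i, j - 1] - gap_open - gap_ext, F[i, j - 1] - gap_ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

random_aa_string <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               len, replace = TRUE), collapse = "")
}

# Directed match table from a score matrix (rows = A genes, cols = D genes),
# symmetric directions, full coverages unless overridden.
matches_from_matrix <- function(M, coverage = 1, min_coverage = 0.6) {
  an <- rownames(M) %||% sprintf("a%d", seq_len(nrow(M)))
  dn <- colnames(M) %||% sprintf("d%d", seq_len(ncol(M)))
  rows <- list()
  cov <- matrix(coverage, nrow(M), ncol(M))
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    for (dirn in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        query = if (dirn == 1) an[i] else dn[j],
        subject = if (dirn == 1) dn[j] else an[i],
        score = M[i, j], percent_identity = 90,
        query_coverage = cov[i, j], subject_coverage = cov[i, j],
        evalue = NA_real_, stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  m$coverage_pass <- pmin(m$query_coverage, m$subject_coverage) >= min_coverage
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force BBH oracle over a score matrix: (i, j) kept iff j is the unique
# argmax of row i (ties -> smallest column name) and i likewise for column j.
bbh_oracle <- function(M) {
  an <- rownames(M); dn <- colnames(M)
  best_row <- vapply(seq_len(nrow(M)), function(i) {
    o <- order(-M[i, ], dn); dn[o[1]]
  }, character(1))
  best_col <- vapply(seq_len(ncol(M)), function(j) {
    o <- order(-M[, j], an); an[o[1]]
  }, character(1))
  out <- list()
  for (i in seq_len(nrow(M))) {
    j <- match(best_row[i], dn)
    if (best_col[j] == an[i]) out[[length(out) + 1L]] <- c(an[i], dn[j])
  }
  if (length(out) == 0L) return(data.frame(gene_a = character(0), gene_d = character(0)))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("gene_a", "gene_d")
  df[order(df$gene_a), , drop = FALSE]
}

# Two-sample KS D statistic by direct ECDF enumeration.
ks_d_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  ex <- vapply(grid, function(g) mean(x <= g), numeric(1))
  ey <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(ex - ey))
}

# One-sided (over-representation) Fisher p by hypergeometric tail enumeration.
fisher_oracle <- function(study_count, study_n, pop_count, pop_n) {
  ks <- study_count:min(study_n, pop_count)
  sum(stats::dhyper(ks, pop_count, pop_n - pop_count, study_n))
}

# Tiny collinear two-subgenome gene order: n genes on one scaffold per
# subgenome, with a 1:1 pair index.
collinear_world <- function(n = 20) {
  genes <- data.frame(
    gene_id = c(sprintf("A_g%02d", 1:n), sprintf("D_g%02d", 1:n)),
    subgenome = rep(c("A", "D"), each = n),
    scaffold = rep(c("A_s1", "D_s1"), each = n),
    position = c(0:(n - 1), 0:(n - 1)),
    stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = sprintf("A_g%02d", 1:n),
                      gene_d = sprintf("D_g%02d", 1:n),
                      stringsAsFactors = FALSE)
  list(genes = genes, pairs = pairs,
       order = homoeologr::gene_order_index(genes),
       index = homoeologr:::partner_index(pairs))
}
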