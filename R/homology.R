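# Homoeolog inference from directed match lists.

# Collapse directed matches into undirected pairs. The per-pair score is the
# maximum over the two directions (BLAST bitscores differ marginally between
# directions); identity/coverages come from the better-scoring direction.
collapse_matches <- function(matches) {
  if (nrow(matches) == 0L) {
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      score = numeric(0), percent_identity = numeric(0),
                      cov1 = numeric(0), cov2 = numeric(0),
                      coverage_pass = logical(0), stringsAsFactors = FALSE))
  }
  g1 <- pmin(matches$query, matches$subject)
  g2 <- pmax(matches$query, matches$subject)
  flip <- matches$query != g1
  cov1 <- ifelse(flip, matches$subject_coverage, matches$query_coverage)
  cov2 <- ifelse(flip, matches$query_coverage, matches$subject_coverage)
  key <- paste(g1, g2, sep = "\r")
  o <- order(key, -matches$score)
  keep <- !duplicated(key[o])
  i <- o[keep]
  data.frame(gene1 = g1[i], gene2 = g2[i], score = matches$score[i],
             percent_identity = matches$percent_identity[i],
             cov1 = cov1[i], cov2 = cov2[i],
             coverage_pass = matches$coverage_pass[i],
             stringsAsFactors = FALSE, row.names = NULL)
}

# Orient undirected pairs so gene_a is on subgenome A. Without a subgenome
# map, gene_a is the lexicographically smaller id.
orient_pairs <- function(pairs, subgenomes = NULL) {
  if (nrow(pairs) == 0L) {
    out <- data.frame(gene_a = character(0), gene_d = character(0))
    return(cbind(out, pairs[, setdiff(names(pairs), c("gene1", "gene2")),
                            drop = FALSE]))
  }
  flip <- rep(FALSE, nrow(pairs))
  if (!is.null(subgenomes)) {
    s1 <- subgenomes[pairs$gene1]; s2 <- subgenomes[pairs$gene2]
    flip <- !is.na(s1) & !is.na(s2) & s1 > s2
  }
  out <- data.frame(gene_a = ifelse(flip, pairs$gene2, pairs$gene1),
                    gene_d = ifelse(flip, pairs$gene1, pairs$gene2),
                    stringsAsFactors = FALSE)
  extra <- pairs[, setdiff(names(pairs), c("gene1", "gene2")), drop = FALSE]
  if ("cov1" %in% names(extra)) {
    ca <- ifelse(flip, extra$cov2, extra$cov1)
    cd <- ifelse(flip, extra$cov1, extra$cov2)
    extra$cov1 <- NULL; extra$cov2 <- NULL
    extra$cov_a <- ca; extra$cov_d <- cd
  }
  cbind(out, extra)
}

# Best partner per gene over a collapsed pair table; ties broken by
# ascending partner id (deterministic).
best_partner <- function(collapsed) {
  long <- data.frame(gene = c(collapsed$gene1, collapsed$gene2),
                     partner = c(collapsed$gene2, collapsed$gene1),
                     score = rep(collapsed$score, 2),
                     stringsAsFactors = FALSE)
  o <- order(long$gene, -long$score, long$partner)
  long <- long[o, , drop = FALSE]
  long <- long[!duplicated(long$gene), , drop = FALSE]
  stats::setNames(long$partner, long$gene)
}

#' Infer bidirectional best hits
#'
#' A pair (a, d) is a BBH iff d is a's highest-scoring match and a is d's
#' highest-scoring match. Ties are broken deterministically (score
#' descending, then partner id ascending), so every gene occurs in at most
#' one BBH pair. No coverage filter is applied (mirroring a plain reciprocal
#' best BLAST hit extraction).
#'
#' @param matches directed match data.frame (see [all_vs_all()])
#' @param subgenomes optional named vector gene id -> subgenome label, used
#'   to put subgenome-A genes in the `gene_a` column
#' @return data.frame: gene_a, gene_d, score, percent_identity, cov_a, cov_d
#' @export
infer_bbh <- function(matches, subgenomes = NULL) {
  cl <- collapse_matches(matches)
  if (nrow(cl) == 0L) return(orient_pairs(cl, subgenomes))
  best <- best_partner(cl)
  keep <- best[cl$gene1] == cl$gene2 & best[cl$gene2] == cl$gene1
  orient_pairs(cl[keep, , drop = FALSE], subgenomes)
}

#' Infer a relaxed many-to-many homoeolog set
#'
#' Coverage-filtered surrogate for "mutually closest within a tolerance":
#' a pair is kept iff its coverage passes and its score is within a relative
#' tolerance `epsilon` of the best score of *both* of its genes. With
#' `epsilon = 0` this reduces to mutually-best pairs (ties included), and a
#' gene duplicated after subgenome divergence can retain several relations,
#' so 1:many and many:many relations are allowed.
#'
#' @param matches directed match data.frame
#' @param epsilon relative score tolerance (>= 0; default 0.05)
#' @param min_coverage minimum of query and subject coverage (default 0.60)
#' @param subgenomes optional gene id -> subgenome map (see [infer_bbh()])
#' @return data.frame of pairs as in [infer_bbh()]
#' @export
infer_homoeologs_tolerant <- function(matches, epsilon = 0.05,
                                      min_coverage = 0.60, subgenomes = NULL) {
  if (!is.numeric(epsilon) || epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  cl <- collapse_matches(matches)
  cl <- cl[pmin(cl$cov1, cl$cov2) >= min_coverage, , drop = FALSE]
  if (nrow(cl) == 0L) return(orient_pairs(cl, subgenomes))
  best_score <- tapply(rep(cl$score, 2), c(cl$gene1, cl$gene2), max)
  keep <- cl$score >= (1 - epsilon) * best_score[cl$gene1] &
          cl$score >= (1 - epsilon) * best_score[cl$gene2]
  orient_pairs(cl[keep, , drop = FALSE], subgenomes)
}

#' Flag hidden paralogs with an outgroup "witness of nonhomoeology"
#'
#' A candidate pair (a, d) is flagged as a likely hidden paralog when a's best
#' outgroup match and d's best outgroup match are two *distinct* outgroup
#' genes that are more similar to their respective in-pair partner than to
#' each other -- the signature of an outgroup-internal duplication older than
#' the subgenome split, with complementary copy losses in the two subgenomes.
#' With no outgroup data the input passes through unchanged.
#'
#' @param candidate_pairs data.frame with gene_a, gene_d columns
#' @param outgroup_matches NULL, or a list with directed match data.frames:
#'   `a` (subgenome A vs outgroup), `d` (subgenome D vs outgroup) and
#'   `outgroup` (outgroup internal, self-hits ignored)
#' @return list: `retained` and `flagged` data.frames; `flagged` gains
#'   columns `witness_a` and `witness_d` with the two outgroup genes
#' @export
witness_filter <- function(candidate_pairs, outgroup_matches = NULL) {
  empty_flag <- function() {
    f <- candidate_pairs[0, , drop = FALSE]
    f$witness_a <- character(0); f$witness_d <- character(0)
    f
  }
  if (is.null(outgroup_matches) ||
      (nrow(outgroup_matches$a %||% empty_matches()) == 0L &&
       nrow(outgroup_matches$d %||% empty_matches()) == 0L)) {
    return(list(retained = candidate_pairs, flagged = empty_flag()))
  }
  best_out <- function(m) {
    if (is.null(m) || nrow(m) == 0L) return(character(0))
    o <- order(m$query, -m$score, m$subject)
    m <- m[o, , drop = FALSE]
    m <- m[!duplicated(m$query), , drop = FALSE]
    stats::setNames(m$subject, m$query)
  }
  ba <- best_out(outgroup_matches$a)
  bd <- best_out(outgroup_matches$d)
  score_of <- function(m, g, h) {
    if (is.null(m) || nrow(m) == 0L) return(-Inf)
    hit <- (m$query == g & m$subject == h) | (m$query == h & m$subject == g)
    if (!any(hit)) -Inf else max(m$score[hit])
  }
  oo <- outgroup_matches$outgroup
  n <- nrow(candidate_pairs)
  flagged <- logical(n)
  wa <- rep(NA_character_, n); wd <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    a <- candidate_pairs$gene_a[i]; d <- candidate_pairs$gene_d[i]
    oa <- ba[a]; od <- bd[d]
    if (is.na(oa) || is.na(od) || oa == od) next
    s_a <- score_of(outgroup_matches$a, a, oa)
    s_d <- score_of(outgroup_matches$d, d, od)
    s_oo <- score_of(oo, oa, od)
    if (s_oo < min(s_a, s_d)) {
      flagged[i] <- TRUE; wa[i] <- oa; wd[i] <- od
    }
  }
  fl <- candidate_pairs[flagged, , drop = FALSE]
  fl$witness_a <- wa[flagged]; fl$witness_d <- wd[flagged]
  list(retained = candidate_pairs[!flagged, , drop = FALSE], flagged = fl)
}

#' Estimate evolutionary distance from percent identity
#'
#' Kimura-style correction for multiple substitutions, reported on a PAM-like
#' scale (1 unit = the amount of evolution changing on average 1% of amino
#' acids): d = -100 ln(1 - p - 0.2 p^2), with p the observed fraction of
#' differing residues. The correction saturates: p >= 0.85 is outside its
#' domain and raises an error. Estimates from identity are not comparable to
#' distances read from a curated all-vs-all database; treat them as relative.
#'
#' @param percent_identity percent identity in (0, 100]
#' @return estimated distance(s), PAM-like units
#' @export
estimate_pam_distance <- function(percent_identity) {
  if (any(!is.finite(percent_identity)) ||
      any(percent_identity <= 0 | percent_identity > 100)) {
    stop("percent_identity must be in (0, 100]", call. = FALSE)
  }
  p <- 1 - percent_identity / 100
  if (any(p >= 0.85)) {
    stop("identity too low: distance correction saturates for p >= 0.85",
         call. = FALSE)
  }
  -100 * log(1 - p - 0.2 * p^2)
}
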