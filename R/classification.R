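# Four-way BBH-by-synteny classification and the pair-set accounting.

#' The four homoeolog categories
#' @export
CATEGORY_LABELS <- c("BBH_syntenic", "BBH_nonsyntenic",
                     "nonBBH_syntenic", "nonBBH_nonsyntenic")

#' Classify one pair from BBH status and synteny score
#'
#' Nonsyntenic means synteny score exactly 0; any positive score is syntenic.
#' Pairs without a computable synteny score (small scaffolds) are excluded.
#'
#' @param is_bbh logical
#' @param synteny_score score in \[0, 1\] or NA
#' @return one of [CATEGORY_LABELS] or "excluded"
#' @export
classify_pair <- function(is_bbh, synteny_score) {
  stopifnot(length(is_bbh) == length(synteny_score))
  out <- ifelse(is.na(synteny_score), "excluded",
         ifelse(is_bbh & synteny_score > 0, "BBH_syntenic",
         ifelse(is_bbh, "BBH_nonsyntenic",
         ifelse(synteny_score > 0, "nonBBH_syntenic", "nonBBH_nonsyntenic"))))
  out
}

#' 2x2 contingency table of the classified pair set
#'
#' @param categories character vector of category labels (excluded entries are
#'   dropped with a count)
#' @return list: `counts` (named, four categories), `total`,
#'   `n_excluded`, and percentage summaries (half-up, 1 decimal):
#'   `pct_bbh_syntenic`, `pct_not_bbh_syntenic` (either nonsyntenic, non-BBH,
#'   or both) and `pct_nonbbh_nonsyntenic` (both)
#' @export
contingency_table <- function(categories) {
  n_excl <- sum(categories == "excluded")
  categories <- categories[categories != "excluded"]
  bad <- setdiff(unique(categories), CATEGORY_LABELS)
  if (length(bad) > 0L) stop("unknown category label(s): ",
                             paste(bad, collapse = ", "), call. = FALSE)
  counts <- vapply(CATEGORY_LABELS, function(l) sum(categories == l), integer(1))
  total <- sum(counts)
  pct <- function(x) if (total == 0) NA_real_ else round_half_up(100 * x / total, 1)
  list(counts = counts, total = total, n_excluded = n_excl,
       pct_bbh_syntenic = pct(counts[["BBH_syntenic"]]),
       pct_not_bbh_syntenic = pct(total - counts[["BBH_syntenic"]]),
       pct_nonbbh_nonsyntenic = pct(counts[["nonBBH_nonsyntenic"]]))
}

#' Overlap accounting between two homoeolog pair sets
#'
#' Compares a comprehensive (method 1, e.g. relaxed many-to-many) and a
#' stricter (method 2, e.g. BBH) undirected pair set, reporting shared and
#' method-specific counts with percentages, and decomposing the
#' method-2-only pairs into those that failed the alignment-coverage filter,
#' those flagged as paralogs by the witness check, and the residual.
#'
#' @param pairs1,pairs2 data.frames with gene_a, gene_d (method 1 and 2)
#' @param coverage_fail_keys,paralog_keys character vectors of pair keys
#'   (`paste(gene_a, gene_d)`) annotating method-2-only pairs
#' @return list of class `overlap_report`
#' @export
overlap_stats <- function(pairs1, pairs2,
                          coverage_fail_keys = character(0),
                          paralog_keys = character(0)) {
  k1 <- unique(pair_key(pairs1$gene_a, pairs1$gene_d))
  k2 <- unique(pair_key(pairs2$gene_a, pairs2$gene_d))
  shared <- intersect(k1, k2)
  only2 <- setdiff(k2, k1)
  cov_fail <- intersect(only2, coverage_fail_keys)
  paralog <- intersect(setdiff(only2, cov_fail), paralog_keys)
  res <- list(n_method1 = length(k1), n_method2 = length(k2),
              n_shared = length(shared),
              n_only1 = length(k1) - length(shared),
              n_only2 = length(only2),
              pct_of_method1 = round_half_up(100 * length(shared) /
                                               max(1L, length(k1)), 1),
              pct_of_method2 = round_half_up(100 * length(shared) /
                                               max(1L, length(k2)), 1),
              only2_coverage_fail = length(cov_fail),
              only2_paralog_flagged = length(paralog),
              only2_residual = length(only2) - length(cov_fail) - length(paralog))
  class(res) <- "overlap_report"
  res
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Pair-set overlap: %d vs %d, shared %d (%.1f%% of set 1, %.1f%% of set 2)\n",
              x$n_method1, x$n_method2, x$n_shared,
              x$pct_of_method1, x$pct_of_method2))
  cat(sprintf("  set-2-only: %d (coverage fail %d, paralog flagged %d, residual %d)\n",
              x$n_only2, x$only2_coverage_fail, x$only2_paralog_flagged,
              x$only2_residual))
  invisible(x)
}

#' Gene-centric deduplicated sets per category
#'
#' For each category, the union of both genes of its pairs with redundancy
#' removed: a gene appears at most once per category, though it may appear in
#' several categories.
#'
#' @param pairs data.frame with gene_a, gene_d, category
#' @return named list of character vectors (one per occupied category)
#' @export
gene_centric_sets <- function(pairs) {
  pairs <- pairs[pairs$category %in% CATEGORY_LABELS, , drop = FALSE]
  out <- lapply(split(pairs, pairs$category),
                function(p) sort(unique(c(p$gene_a, p$gene_d))))
  out[lengths(out) > 0L]
}
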