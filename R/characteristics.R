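# Per-gene and per-pair characteristic metrics across categories.

#' Number of homoeologous relations per gene
#'
#' A value of 1 means the gene sits in a strict 1:1 relation; larger values
#' indicate surviving duplicates (larger multigene families). Summed over all
#' genes the counts equal twice the number of pairs.
#'
#' @param genes character vector of gene ids
#' @param all_pairs data.frame with gene_a, gene_d covering the full
#'   homoeolog set
#' @return named integer vector of relation counts
#' @export
nb_homoeologous_pairs <- function(genes, all_pairs) {
  tab <- table(c(all_pairs$gene_a, all_pairs$gene_d))
  counts <- as.integer(tab[genes])
  if (anyNA(counts)) {
    stop("gene(s) with no homoeolog relation: ",
         paste(utils::head(genes[is.na(counts)], 5), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(counts, genes)
}

#' Per-category median and mean of a metric
#'
#' @param values_by_category named list of numeric vectors
#' @return data.frame: category, n, median, mean (empty categories absent)
#' @export
summarize_metric <- function(values_by_category) {
  values_by_category <- values_by_category[lengths(values_by_category) > 0L]
  if (length(values_by_category) == 0L) {
    return(data.frame(category = character(0), n = integer(0),
                      median = numeric(0), mean = numeric(0)))
  }
  data.frame(category = names(values_by_category),
             n = vapply(values_by_category, length, integer(1)),
             median = vapply(values_by_category, stats::median, numeric(1)),
             mean = vapply(values_by_category, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise two-sample Kolmogorov-Smirnov tests between categories
#'
#' Two-sided test for every unordered pair of categories; D is the supremum
#' gap between the two ECDFs and the p-value is asymptotic. Comparisons where
#' either sample has fewer than 2 values are skipped with a warning.
#'
#' @param values_by_category named list of numeric vectors
#' @return data.frame: category1, category2, n1, n2, D, p_value
#' @export
ks_all_pairs <- function(values_by_category) {
  cats <- names(values_by_category)
  rows <- list()
  if (length(cats) >= 2L) {
    for (i in seq_len(length(cats) - 1L)) for (j in seq(i + 1L, length(cats))) {
      x <- values_by_category[[i]]; y <- values_by_category[[j]]
      if (length(x) < 2L || length(y) < 2L) {
        warning(sprintf("skipping KS test %s vs %s: fewer than 2 values",
                        cats[i], cats[j]), call. = FALSE)
        next
      }
      kt <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided",
                                            exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        category1 = cats[i], category2 = cats[j],
        n1 = length(x), n2 = length(y),
        D = unname(kt$statistic), p_value = kt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(category1 = character(0), category2 = character(0),
                      n1 = integer(0), n2 = integer(0),
                      D = numeric(0), p_value = numeric(0)))
  }
  do.call(rbind, rows)
}
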