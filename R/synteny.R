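# Window-based synteny scoring over gene order.

#' Build a gene-order index
#'
#' @param genes data.frame with gene_id, subgenome, scaffold, position
#' @return object of class `gene_order`: per-scaffold ordered id vectors plus
#'   a per-gene locator
#' @export
gene_order_index <- function(genes) {
  stop_if_not_df_cols(genes, c("gene_id", "scaffold", "position"), "gene order")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids in gene order", call. = FALSE)
  genes <- genes[order(genes$scaffold, genes$position), , drop = FALSE]
  scaffolds <- split(genes$gene_id, genes$scaffold)
  pos <- stats::setNames(unlist(lapply(scaffolds, seq_along), use.names = FALSE) - 1L,
                         unlist(scaffolds, use.names = FALSE))
  scaf <- stats::setNames(rep(names(scaffolds), lengths(scaffolds)),
                          unlist(scaffolds, use.names = FALSE))
  structure(list(scaffolds = scaffolds, position = pos, scaffold = scaf),
            class = "gene_order")
}

#' Genes in the window around a focal gene
#'
#' Up to `half_window` genes on each side of the focal gene on its scaffold,
#' truncated at scaffold ends; the focal gene itself is excluded.
#'
#' @param gene focal gene id
#' @param gene_order a [gene_order_index()]
#' @param half_window genes per side (default 5)
#' @return character vector of neighbour gene ids (possibly empty)
#' @export
neighbor_window <- function(gene, gene_order, half_window = 5) {
  sc <- gene_order$scaffold[gene]
  if (is.na(sc)) stop(sprintf("unknown gene: %s", gene), call. = FALSE)
  v <- gene_order$scaffolds[[sc]]
  i <- gene_order$position[[gene]] + 1L
  lo <- max(1L, i - half_window); hi <- min(length(v), i + half_window)
  v[setdiff(seq(lo, hi), i)]
}

# Partner lookup: gene id -> character vector of its homoeologous partners.
partner_index <- function(pairs) {
  long <- data.frame(gene = c(pairs$gene_a, pairs$gene_d),
                     partner = c(pairs$gene_d, pairs$gene_a),
                     stringsAsFactors = FALSE)
  split(long$partner, long$gene)
}

#' Synteny score of one homoeolog pair
#'
#' Pooled-fraction definition: over the two windows W_A (around gene_a) and
#' W_D (around gene_d), the score is the number of W_A genes with at least one
#' homoeologous counterpart in W_D, plus the number of W_D genes with at least
#' one counterpart in W_A, divided by |W_A| + |W_D|. The homoeolog index must
#' contain *all* inferred relations (the comprehensive many-to-many set), not
#' only BBHs. Undefined (NA, with a reason) when either window has fewer than
#' `min_neighbors` genes -- the small-scaffold exclusion.
#'
#' @param gene_a,gene_d the two genes of the pair
#' @param index a [partner_index()]-style list (gene -> partners)
#' @param gene_order a [gene_order_index()] covering both subgenomes
#' @param half_window,min_neighbors window parameters (defaults 5 and 2)
#' @return list: `score` (in \[0,1\] or NA), `reason` (NA or "small_scaffold")
#' @export
synteny_score <- function(gene_a, gene_d, index, gene_order,
                          half_window = 5, min_neighbors = 2) {
  if (is.na(gene_order$scaffold[gene_a]) || is.na(gene_order$scaffold[gene_d])) {
    return(list(score = NA_real_, reason = "small_scaffold"))
  }
  wa <- neighbor_window(gene_a, gene_order, half_window)
  wd <- neighbor_window(gene_d, gene_order, half_window)
  if (length(wa) < min_neighbors || length(wd) < min_neighbors) {
    return(list(score = NA_real_, reason = "small_scaffold"))
  }
  partners_of <- function(g) index[[g]] %||% character(0)
  a_hit <- vapply(wa, function(g) any(partners_of(g) %in% wd), logical(1))
  d_hit <- vapply(wd, function(g) any(partners_of(g) %in% wa), logical(1))
  list(score = (sum(a_hit) + sum(d_hit)) / (length(wa) + length(wd)),
       reason = NA_character_)
}

#' Score all homoeolog pairs
#'
#' @param pairs data.frame with gene_a, gene_d
#' @param index partner index over the full homoeolog set
#' @param gene_order a [gene_order_index()]
#' @param half_window,min_neighbors see [synteny_score()]
#' @return list: `pairs` (input plus `synteny_score`, `excluded_reason`),
#'   `n_excluded`
#' @export
score_all_pairs <- function(pairs, index, gene_order,
                            half_window = 5, min_neighbors = 2) {
  n <- nrow(pairs)
  sc <- rep(NA_real_, n); reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- synteny_score(pairs$gene_a[i], pairs$gene_d[i], index, gene_order,
                       half_window, min_neighbors)
    sc[i] <- r$score; reason[i] <- r$reason
  }
  pairs$synteny_score <- sc
  pairs$excluded_reason <- reason
  list(pairs = pairs, n_excluded = sum(!is.na(reason)))
}

#' Histogram of synteny scores
#'
#' Eleven bins by default: the first holds scores exactly 0 (the nonsyntenic
#' pairs); the remaining bins partition (0, 1] into right-closed intervals
#' (0, 0.1], (0.1, 0.2], ..., (0.9, 1].
#'
#' @param scores numeric scores in \[0, 1\] (NAs dropped)
#' @param n_bins total number of bins (default 11)
#' @return named integer vector of counts
#' @export
bin_scores <- function(scores, n_bins = 11) {
  scores <- scores[!is.na(scores)]
  if (any(scores < 0 | scores > 1)) stop("scores must be in [0, 1]", call. = FALSE)
  k <- n_bins - 1L
  breaks <- seq(0, 1, length.out = k + 1L)
  pos <- table(cut(scores[scores > 0], breaks = breaks, right = TRUE,
                   include.lowest = FALSE))
  counts <- c(sum(scores == 0), as.integer(pos))
  names(counts) <- c("0", levels(cut(numeric(0), breaks = breaks, right = TRUE)))
  counts
}
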