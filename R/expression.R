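# Condition-level expression flags, breadth and level from sample-level TPM.

#' Read kallisto abundance tables into a TPM matrix
#'
#' Each file must have the kallisto `abundance.tsv` layout (columns
#' target_id, length, eff_length, est_counts, tpm). `target_id` is taken as
#' the gene id: fixtures here are gene-level, and no transcript-to-gene
#' aggregation is performed (a documented limitation for real kallisto runs).
#' All files must cover the same gene set; a gene missing from one sample is
#' an error, never a silent zero.
#'
#' @param paths named character vector: sample name -> abundance.tsv path
#' @param design data.frame with columns sample, condition
#' @return numeric matrix genes x samples with a `"design"` attribute
#' @export
read_abundance <- function(paths, design) {
  stop_if_not_df_cols(design, c("sample", "condition"), "design")
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("paths must be named by sample", call. = FALSE)
  }
  unknown <- setdiff(names(paths), design$sample)
  if (length(unknown) > 0L) {
    stop("sample(s) not in design: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cols <- c("target_id", "length", "eff_length", "est_counts", "tpm")
  mats <- lapply(names(paths), function(s) {
    tab <- utils::read.table(paths[[s]], sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    if (!identical(names(tab), cols)) {
      stop(sprintf("%s: malformed header (expected %s)", paths[[s]],
                   paste(cols, collapse = ", ")), call. = FALSE)
    }
    if (anyDuplicated(tab$target_id)) {
      stop(sprintf("%s: duplicated target_id", paths[[s]]), call. = FALSE)
    }
    stats::setNames(tab$tpm, tab$target_id)
  })
  genes <- names(mats[[1]])
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(paths),
              dimnames = list(genes, names(paths)))
  for (k in seq_along(mats)) {
    v <- mats[[k]][genes]
    if (anyNA(v) || length(mats[[k]]) != length(genes)) {
      stop(sprintf("sample %s does not cover the same gene set", names(paths)[k]),
           call. = FALSE)
    }
    m[, k] <- v
  }
  attr(m, "design") <- design[match(colnames(m), design$sample), , drop = FALSE]
  m
}

#' Average time-point samples into condition-level TPM
#'
#' @param tpm genes x samples matrix
#' @param design data.frame sample, condition covering every column
#' @return genes x conditions matrix of arithmetic means (single-sample
#'   conditions pass through)
#' @export
average_timepoints <- function(tpm, design) {
  stop_if_not_df_cols(design, c("sample", "condition"), "design")
  design <- design[design$sample %in% colnames(tpm), , drop = FALSE]
  missing <- setdiff(colnames(tpm), design$sample)
  if (length(missing) > 0L) {
    stop("sample(s) without a condition: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  conditions <- unique(design$condition)
  out <- vapply(conditions, function(cn) {
    cols <- design$sample[design$condition == cn]
    if (length(cols) == 0L) stop("condition with zero samples: ", cn, call. = FALSE)
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(tpm), conditions))
  out
}

#' Expression flags, breadth and level per gene
#'
#' A gene is expressed in a condition when its condition-level TPM is at or
#' above `threshold` (inclusive). Breadth counts expressing conditions;
#' level is the mean TPM across *all* conditions, including sub-threshold
#' ones; `expressed` is breadth >= 1.
#'
#' @param condition_tpm genes x conditions matrix
#' @param threshold TPM threshold (> 0; default 2)
#' @return data.frame: gene_id, breadth, level, expressed
#' @export
breadth_and_level <- function(condition_tpm, threshold = 2) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  breadth <- as.integer(rowSums(condition_tpm >= threshold))
  data.frame(gene_id = rownames(condition_tpm),
             breadth = breadth,
             level = rowMeans(condition_tpm),
             expressed = breadth >= 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-category expression summary
#'
#' Percentage of each category's genes expressed at all, plus breadth and
#' level value lists restricted to the expressed genes (the inputs for the
#' distribution comparisons). Genes without an expression record count as not
#' expressed and are tallied in `n_missing`.
#'
#' @param records output of [breadth_and_level()]
#' @param sets gene-centric category sets from [gene_centric_sets()]
#' @return list per category: n, n_expressed, pct_expressed (half-up, 1
#'   decimal), n_missing, breadth (vector), level (vector)
#' @export
category_expression_summary <- function(records, sets) {
  lookup <- records[!duplicated(records$gene_id), , drop = FALSE]
  rownames(lookup) <- lookup$gene_id
  out <- lapply(names(sets), function(cat) {
    genes <- sets[[cat]]
    rec <- lookup[intersect(genes, rownames(lookup)), , drop = FALSE]
    n_missing <- length(genes) - nrow(rec)
    expressed <- rec[rec$expressed, , drop = FALSE]
    list(n = length(genes),
         n_expressed = nrow(expressed),
         pct_expressed = round_half_up(100 * nrow(expressed) / max(1L, length(genes)), 1),
         n_missing = n_missing,
         breadth = expressed$breadth,
         level = expressed$level)
  })
  stats::setNames(out, names(sets))
}
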