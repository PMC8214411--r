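# Shared small helpers.

AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported percentages here follow
#' the conventional half-up display rule (e.g. 25.85 -> 25.9).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Canonical key for an oriented homoeolog pair
#'
#' gene_a and gene_d are on fixed sides (subgenome A first), so the key is
#' their separator-joined concatenation.
#'
#' @param gene_a,gene_d gene id vectors
#' @return character vector of keys
#' @export
pair_key <- function(gene_a, gene_d) paste(gene_a, gene_d, sep = "\r")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_df_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

# Deterministic argmax: highest value, ties broken by ascending name order.
which_best <- function(values, names) {
  o <- order(-values, names)
  o[1L]
}
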