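# Plain-text fixture writers and readers (lossless round-trip).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE)
}

#' Write a synthetic dataset to plain-text fixtures
#'
#' Writes per-subgenome protein FASTA (plus outgroup when present), the
#' gene-order TSV (gene_id, subgenome, scaffold, position_index,
#' protein_length), the truth TSV, and optionally an expression TSV with its
#' design TSV, and an OBO subset with its annotation TSV. Everything written
#' is re-readable losslessly by the package's readers.
#'
#' @param dataset a `homoeolog_sim` object
#' @param dir output directory (created if needed)
#' @param expression optional TPM matrix from [simulate_expression()]
#' @param go optional list from [simulate_go()]
#' @return `dir`, invisibly
#' @export
write_fixtures <- function(dataset, dir, expression = NULL, go = NULL) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0L) {
    stop("directory is not writable: ", dir, call. = FALSE)
  }
  g <- dataset$genes
  for (sub in c("A", "D")) {
    ids <- g$gene_id[g$subgenome == sub]
    write_protein_fasta(dataset$proteins[ids],
                        file.path(dir, sprintf("proteins_%s.fasta", sub)))
  }
  if (!is.null(dataset$outgroup_proteins)) {
    write_protein_fasta(dataset$outgroup_proteins, file.path(dir, "outgroup.fasta"))
  }
  go_df <- data.frame(gene_id = g$gene_id, subgenome = g$subgenome,
                      scaffold = g$scaffold, position_index = g$position,
                      protein_length = g$protein_length)
  write_tsv(go_df, file.path(dir, "gene_order.tsv"))
  write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  if (!is.null(expression)) {
    design <- attr(expression, "design")
    write_tsv(cbind(data.frame(gene_id = rownames(expression)),
                    as.data.frame(expression, check.names = FALSE)),
              file.path(dir, "expression.tsv"))
    write_tsv(design, file.path(dir, "design.tsv"))
  }
  if (!is.null(go)) {
    write_obo(go$dag, file.path(dir, "go.obo"))
    write_tsv(go$annotations, file.path(dir, "annotations.tsv"))
  }
  invisible(dir)
}

#' Read a gene-order TSV
#' @param path TSV with columns gene_id, subgenome, scaffold, position_index,
#'   protein_length
#' @return data.frame with the internal column names (position, not
#'   position_index)
#' @export
read_gene_order <- function(path) {
  df <- read_tsv(path)
  stop_if_not_df_cols(df, c("gene_id", "subgenome", "scaffold",
                            "position_index", "protein_length"), path)
  for (cn in c("gene_id", "subgenome", "scaffold")) df[[cn]] <- as.character(df[[cn]])
  for (cn in c("position_index", "protein_length")) df[[cn]] <- as.integer(df[[cn]])
  names(df)[names(df) == "position_index"] <- "position"
  df
}

#' Read protein sequences from FASTA
#' @param path FASTA file
#' @return named character vector
#' @export
read_proteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Read a truth-relation TSV
#' @param path TSV with gene_a, gene_d, event_class, expected_category
#' @return data.frame
#' @export
read_truth <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  stop_if_not_df_cols(df, c("gene_a", "gene_d", "event_class",
                            "expected_category"), path)
  df
}

#' Read an expression TSV (gene_id + one column per sample)
#' @param path expression TSV
#' @return numeric matrix genes x samples
#' @export
read_expression_table <- function(path) {
  df <- read_tsv(path)
  stop_if_not_df_cols(df, "gene_id", path)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read a gene-to-term annotation TSV
#' @param path TSV with gene_id, term_id
#' @return data.frame
#' @export
read_annotations <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  stop_if_not_df_cols(df, c("gene_id", "term_id"), path)
  df
}

#' Write per-sample kallisto-style abundance tables
#'
#' One `<sample>/abundance.tsv` per column of the TPM matrix, in the layout
#' consumed by [read_abundance()]. Lengths default to 3x a 200-residue
#' protein; est_counts are back-computed from TPM for internal consistency.
#'
#' @param tpm genes x samples matrix
#' @param dir output directory
#' @param lengths optional named vector of transcript lengths per gene
#' @return named vector of file paths (by sample)
#' @export
write_kallisto <- function(tpm, dir, lengths = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- rownames(tpm)
  len <- if (is.null(lengths)) stats::setNames(rep(600L, length(genes)), genes)
         else lengths[genes]
  eff <- pmax(1, len - 150)
  paths <- character(0)
  for (s in colnames(tpm)) {
    sd <- file.path(dir, s)
    dir.create(sd, showWarnings = FALSE)
    tab <- data.frame(target_id = genes, length = len, eff_length = eff,
                      est_counts = tpm[, s] * eff / 1000, tpm = tpm[, s])
    write_tsv(tab, file.path(sd, "abundance.tsv"))
    paths[s] <- file.path(sd, "abundance.tsv")
  }
  paths
}
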