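# GO DAG handling, annotation propagation and Fisher enrichment.

#' Construct a GO DAG object
#'
#' @param terms data.frame: id, name, namespace
#' @param parents named list: term id -> character vector of is_a parents
#' @return object of class `go_dag`
#' @export
go_dag <- function(terms, parents) {
  stop_if_not_df_cols(terms, c("id", "name", "namespace"), "terms")
  if (anyDuplicated(terms$id)) stop("duplicate term ids", call. = FALSE)
  missing <- setdiff(terms$id, names(parents))
  parents[missing] <- rep(list(character(0)), length(missing))
  unknown <- setdiff(unlist(parents, use.names = FALSE), terms$id)
  if (length(unknown) > 0L) {
    stop("is_a parent(s) not defined as terms: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  dag <- structure(list(terms = terms, parents = parents[terms$id]),
                   class = "go_dag")
  dag$ancestors <- compute_ancestors(dag)  # also validates acyclicity
  dag
}

# Transitive ancestor closure by memoised DFS; cycles are an error.
compute_ancestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  in_progress <- new.env(parent = emptyenv())
  visit <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    if (isTRUE(in_progress[[id]])) stop("cycle in GO DAG at ", id, call. = FALSE)
    in_progress[[id]] <- TRUE
    ps <- dag$parents[[id]]
    anc <- unique(c(ps, unlist(lapply(ps, visit), use.names = FALSE)))
    in_progress[[id]] <- FALSE
    memo[[id]] <- anc
    anc
  }
  stats::setNames(lapply(dag$terms$id, visit), dag$terms$id)
}

#' @export
print.go_dag <- function(x, ...) {
  roots <- x$terms$id[lengths(x$parents) == 0L]
  cat(sprintf("GO DAG: %d terms, %d root(s) [%s]\n", nrow(x$terms),
              length(roots), paste(roots, collapse = ", ")))
  invisible(x)
}

#' Read a minimal OBO v1.2 file
#'
#' Supports `[Term]` stanzas with id, name, namespace and is_a tags only;
#' obsolete terms and other relationship types are ignored.
#'
#' @param path path to the .obo file
#' @return a [go_dag()]
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  ids <- character(0); nm <- character(0); ns <- character(0)
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !isTRUE(cur$obsolete)) {
      ids <<- c(ids, cur$id); nm <<- c(nm, cur$name %||% cur$id)
      ns <<- c(ns, cur$namespace %||% NA_character_)
      parents[[cur$id]] <<- cur$is_a %||% character(0)
    }
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln))
    if (ln == "[Term]") { flush(); cur <- list(is_a = character(0)); next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; next }
    if (is.null(cur) || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:")) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_a:")) cur$is_a <- c(cur$is_a, trimws(sub("^is_a:", "", ln)))
    else if (ln == "is_obsolete: true") cur$obsolete <- TRUE
  }
  flush()
  go_dag(data.frame(id = ids, name = nm, namespace = ns, stringsAsFactors = FALSE),
         parents)
}

#' Write a minimal OBO v1.2 file
#'
#' @param dag a [go_dag()]
#' @param path output path
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    writeLines(c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
                 if (!is.na(t$namespace)) paste0("namespace: ", t$namespace),
                 paste0("is_a: ", dag$parents[[t$id]], recycle0 = TRUE), ""), con)
  }
  invisible(path)
}

#' Propagate annotations to ancestor terms (true-path closure)
#'
#' A gene annotated to a term is annotated to every ancestor of that term.
#' Idempotent and monotone.
#'
#' @param annotations data.frame: gene_id, term_id
#' @param dag a [go_dag()]
#' @return closed annotation data.frame (unique gene_id x term_id rows)
#' @export
propagate_annotations <- function(annotations, dag) {
  stop_if_not_df_cols(annotations, c("gene_id", "term_id"), "annotations")
  unknown <- setdiff(unique(annotations$term_id), dag$terms$id)
  if (length(unknown) > 0L) {
    stop("annotation to unknown term(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(annotations) == 0L) return(annotations)
  closed <- lapply(seq_len(nrow(annotations)), function(i) {
    t <- annotations$term_id[i]
    data.frame(gene_id = annotations$gene_id[i],
               term_id = c(t, dag$ancestors[[t]]), stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, closed))
  rownames(out) <- NULL
  out
}

#' Fisher exact over-representation test per term
#'
#' For every term annotating at least one study gene, tests over-representation
#' of the term in the study set against the population with a one-sided
#' Fisher exact test on the 2x2 table (in study x has term), and applies
#' Bonferroni correction with family size m = number of tested terms (fixed
#' before any filtering).
#'
#' @param study_genes character vector, a subset of `population_genes`
#' @param population_genes character vector (the background)
#' @param annotations propagated annotation data.frame (gene_id, term_id)
#' @return data.frame: term_id, study_count, study_n, pop_count, pop_n,
#'   p_value, p_bonferroni, enriched (corrected p < 0.05), sorted by p
#' @export
fisher_enrichment <- function(study_genes, population_genes, annotations) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  if (length(study_genes) == 0L) stop("study set is empty", call. = FALSE)
  if (length(setdiff(study_genes, population_genes)) > 0L) {
    stop("study set must be a subset of the population", call. = FALSE)
  }
  ann <- annotations[annotations$gene_id %in% population_genes, , drop = FALSE]
  ann <- unique(ann)
  genes_of <- split(ann$gene_id, ann$term_id)
  study_n <- length(study_genes); pop_n <- length(population_genes)
  terms <- names(genes_of)[vapply(genes_of, function(g)
    any(g %in% study_genes), logical(1))]
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), study_count = integer(0),
                      study_n = integer(0), pop_count = integer(0),
                      pop_n = integer(0), p_value = numeric(0),
                      p_bonferroni = numeric(0), enriched = logical(0)))
  }
  m <- length(terms)
  rows <- lapply(terms, function(t) {
    g <- genes_of[[t]]
    sc <- sum(g %in% study_genes); pc <- length(g)
    tab <- matrix(c(sc, study_n - sc, pc - sc, pop_n - study_n - (pc - sc)), 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term_id = t, study_count = sc, study_n = study_n,
               pop_count = pc, pop_n = pop_n, p_value = p,
               p_bonferroni = min(1, p * m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$enriched <- out$p_bonferroni < 0.05
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep Bonferroni-significant enrichment rows
#'
#' @param rows output of [fisher_enrichment()]
#' @param alpha significance level on the corrected p (default 0.05)
#' @return the significant subset
#' @export
bonferroni_filter <- function(rows, alpha = 0.05) {
  rows[rows$p_bonferroni < alpha, , drop = FALSE]
}

#' Per-category proportion of genes annotated with given terms
#'
#' @param sets gene-centric category sets ([gene_centric_sets()])
#' @param annotations propagated annotation data.frame
#' @param terms character vector of term ids (a gene counts if it carries any)
#' @param dag optional [go_dag()]; when supplied, `terms` must exist in it
#' @return named numeric vector of proportions in \[0, 1\]
#' @export
term_proportions <- function(sets, annotations, terms, dag = NULL) {
  if (!is.null(dag)) {
    unknown <- setdiff(terms, dag$terms$id)
    if (length(unknown) > 0L) {
      stop("unknown term id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  carriers <- unique(annotations$gene_id[annotations$term_id %in% terms])
  vapply(sets, function(g) {
    if (length(g) == 0L) return(NA_real_)
    sum(g %in% carriers) / length(g)
  }, numeric(1))
}
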