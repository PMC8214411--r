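# End-to-end orchestration: homology -> synteny -> classification ->
# characteristics -> expression -> enrichment, with TSV/JSON outputs.

#' Pipeline configuration
#'
#' @param fasta_a,fasta_d protein FASTA per subgenome
#' @param gene_order gene-order TSV (see [read_gene_order()])
#' @param out_dir output directory
#' @param blast optional precomputed 14-column BLAST tabular covering both
#'   directions (skips the alignment stage)
#' @param outgroup_fasta optional outgroup proteome for the witness check
#' @param expression,design optional expression TSV and design TSV
#' @param obo,annotations optional GO DAG subset and annotation TSV
#' @param min_coverage,epsilon,half_window,min_neighbors,tpm_threshold,alpha
#'   analysis parameters (defaults 0.60, 0.05, 5, 2, 2, 0.05)
#' @param engine alignment engine for [all_vs_all()]
#' @param report_terms optional term ids for the per-category
#'   annotated-proportion summary
#' @param seed integer seed recorded with the run
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(fasta_a, fasta_d, gene_order, out_dir,
                            blast = NULL, outgroup_fasta = NULL,
                            expression = NULL, design = NULL,
                            obo = NULL, annotations = NULL,
                            min_coverage = 0.60, epsilon = 0.05,
                            half_window = 5, min_neighbors = 2,
                            tpm_threshold = 2, alpha = 0.05,
                            engine = "auto", report_terms = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

pam_or_na <- function(percent_identity) {
  p <- 1 - percent_identity / 100
  ok <- is.finite(p) & p < 0.85 & percent_identity > 0
  out <- rep(NA_real_, length(p))
  out[ok] <- estimate_pam_distance(percent_identity[ok])
  out
}

#' Run the full homoeolog analysis
#'
#' Stages: cross-subgenome similarity (computed or ingested), BBH and
#' relaxed many-to-many inference, outgroup witness filtering, window synteny
#' scoring, four-way classification with contingency/overlap accounting,
#' per-category characteristics with KS tests, expression summaries, and GO
#' enrichment. Optional stages are skipped with a logged notice when their
#' inputs are absent. All intermediate tables are written as TSV under
#' `out_dir` together with `report.json` and a resolved-config copy.
#'
#' @param config a [pipeline_config()]
#' @return the report, invisibly (class `homoeolog_report`)
#' @export
run_pipeline <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = config[c("min_coverage", "epsilon", "half_window",
                                       "min_neighbors", "tpm_threshold",
                                       "alpha", "seed")])

  genes <- stage("inputs", read_gene_order(config$gene_order))
  n_drop <- sum(!genes$subgenome %in% c("A", "D"))
  if (n_drop > 0L) {
    message(sprintf("dropping %d gene(s) without subgenome assignment", n_drop))
  }
  report$counts <- list(genes_dropped_no_subgenome = n_drop)
  genes <- genes[genes$subgenome %in% c("A", "D"), , drop = FALSE]
  proteins <- stage("inputs", {
    p <- c(read_proteins(config$fasta_a), read_proteins(config$fasta_d))
    p[names(p) %in% genes$gene_id]
  })
  subgenomes <- stats::setNames(genes$subgenome, genes$gene_id)
  prot_a <- proteins[names(proteins) %in% genes$gene_id[genes$subgenome == "A"]]
  prot_d <- proteins[names(proteins) %in% genes$gene_id[genes$subgenome == "D"]]

  matches <- stage("homology", {
    if (!is.null(config$blast)) {
      read_blast_tabular(config$blast, min_coverage = config$min_coverage)
    } else {
      rbind(all_vs_all(prot_a, prot_d, min_coverage = config$min_coverage,
                       engine = config$engine),
            all_vs_all(prot_d, prot_a, min_coverage = config$min_coverage,
                       engine = config$engine))
    }
  })
  message(sprintf("homology: %d directed matches", nrow(matches)))

  bbh <- stage("bbh", infer_bbh(matches, subgenomes))
  tolerant <- stage("tolerant",
    infer_homoeologs_tolerant(matches, epsilon = config$epsilon,
                              min_coverage = config$min_coverage,
                              subgenomes = subgenomes))
  message(sprintf("inference: %d BBH pairs, %d tolerant pairs",
                  nrow(bbh), nrow(tolerant)))

  flagged <- NULL
  comprehensive <- tolerant
  if (!is.null(config$outgroup_fasta)) {
    wit <- stage("witness", {
      og <- read_proteins(config$outgroup_fasta)
      oo <- all_vs_all(og, og, min_coverage = 0, engine = config$engine)
      oo <- oo[oo$query != oo$subject, , drop = FALSE]
      witness_filter(tolerant, list(
        a = all_vs_all(prot_a, og, min_coverage = 0, engine = config$engine),
        d = all_vs_all(prot_d, og, min_coverage = 0, engine = config$engine),
        outgroup = oo))
    })
    comprehensive <- wit$retained
    flagged <- wit$flagged
    message(sprintf("witness: flagged %d pair(s) as hidden paralogs", nrow(flagged)))
  } else {
    message("witness: no outgroup provided, stage skipped")
  }

  scored <- stage("synteny", {
    idx <- partner_index(comprehensive)
    gorder <- gene_order_index(genes)
    score_all_pairs(comprehensive, idx, gorder,
                    half_window = config$half_window,
                    min_neighbors = config$min_neighbors)
  })
  pairs <- scored$pairs
  pairs$pam_estimate <- pam_or_na(pairs$percent_identity)
  pairs$is_bbh <- pair_key(pairs$gene_a, pairs$gene_d) %in%
    pair_key(bbh$gene_a, bbh$gene_d)
  pairs$category <- classify_pair(pairs$is_bbh, pairs$synteny_score)
  message(sprintf("synteny: %d scored, %d excluded (small scaffold)",
                  nrow(pairs) - scored$n_excluded, scored$n_excluded))

  contingency <- stage("classification", contingency_table(pairs$category))
  overlap <- stage("classification", {
    cl <- collapse_matches(matches)
    cov_fail <- cl[!(pmin(cl$cov1, cl$cov2) >= config$min_coverage), , drop = FALSE]
    cov_fail_or <- orient_pairs(cov_fail, subgenomes)
    overlap_stats(comprehensive, bbh,
                  coverage_fail_keys = pair_key(cov_fail_or$gene_a, cov_fail_or$gene_d),
                  paralog_keys = if (is.null(flagged)) character(0) else
                    pair_key(flagged$gene_a, flagged$gene_d))
  })

  sets <- gene_centric_sets(pairs)
  characteristics <- stage("characteristics", {
    nb <- nb_homoeologous_pairs(unique(c(comprehensive$gene_a, comprehensive$gene_d)),
                                comprehensive)
    plen <- stats::setNames(genes$protein_length, genes$gene_id)
    by_cat <- function(vals) lapply(sets, function(g) unname(vals[g]))
    pam_by_cat <- lapply(split(pairs$pam_estimate, pairs$category),
                         function(v) v[!is.na(v)])
    pam_by_cat <- pam_by_cat[intersect(CATEGORY_LABELS, names(pam_by_cat))]
    metrics <- list(nb_homoeologous_pairs = by_cat(nb),
                    protein_length = by_cat(plen),
                    pam_distance = pam_by_cat)
    list(metrics = metrics,
         summary = lapply(metrics, summarize_metric),
         ks = lapply(metrics, function(m) suppressWarnings(ks_all_pairs(m))))
  })

  expression_summary <- NULL
  if (!is.null(config$expression) && !is.null(config$design)) {
    expression_summary <- stage("expression", {
      tpm <- read_expression_table(config$expression)
      design <- read_tsv(config$design, colClasses = "character")
      cond <- average_timepoints(tpm, design)
      rec <- breadth_and_level(cond, threshold = config$tpm_threshold)
      summ <- category_expression_summary(rec, sets)
      ks <- list(
        breadth = suppressWarnings(ks_all_pairs(lapply(summ, `[[`, "breadth"))),
        level = suppressWarnings(ks_all_pairs(lapply(summ, `[[`, "level"))))
      list(records = rec, summary = summ, ks = ks)
    })
  } else message("expression: inputs absent, stage skipped")

  enrichment <- NULL
  if (!is.null(config$obo) && !is.null(config$annotations)) {
    enrichment <- stage("enrichment", {
      dag <- read_obo(config$obo)
      ann <- propagate_annotations(read_annotations(config$annotations), dag)
      population <- unique(unlist(sets, use.names = FALSE))
      res <- lapply(sets, function(g) fisher_enrichment(g, population, ann))
      props <- if (!is.null(config$report_terms)) {
        term_proportions(sets, ann, config$report_terms, dag)
      }
      list(per_category = res, term_proportions = props)
    })
  } else message("enrichment: inputs absent, stage skipped")

  # ---- outputs -------------------------------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  write_tsv(pairs, out("pairs.tsv"))
  if (!is.null(flagged)) write_tsv(flagged, out("flagged_pairs.tsv"))
  hist <- bin_scores(pairs$synteny_score)
  write_tsv(data.frame(bin = names(hist), count = as.integer(hist)),
            out("synteny_histogram.tsv"))
  for (m in names(characteristics$summary)) {
    write_tsv(characteristics$summary[[m]], out(sprintf("summary_%s.tsv", m)))
    write_tsv(characteristics$ks[[m]], out(sprintf("ks_%s.tsv", m)))
  }
  if (!is.null(enrichment)) {
    for (cat in names(enrichment$per_category)) {
      write_tsv(enrichment$per_category[[cat]],
                out(sprintf("enrichment_%s.tsv", cat)))
    }
  }

  report$counts <- c(report$counts, list(
    genes = nrow(genes), directed_matches = nrow(matches),
    bbh_pairs = nrow(bbh), tolerant_pairs = nrow(tolerant),
    witness_flagged = if (is.null(flagged)) NA_integer_ else nrow(flagged),
    comprehensive_pairs = nrow(comprehensive),
    scored_pairs = contingency$total, excluded_pairs = contingency$n_excluded))
  report$contingency <- contingency
  report$overlap <- unclass(overlap)
  report$synteny_histogram <- as.list(hist)
  report$characteristics_summary <- characteristics$summary
  if (!is.null(expression_summary)) {
    report$expression <- lapply(expression_summary$summary, function(s)
      s[c("n", "n_expressed", "pct_expressed", "n_missing")])
  }
  if (!is.null(enrichment)) {
    report$enrichment <- lapply(enrichment$per_category, function(r) {
      sig <- bonferroni_filter(r, config$alpha)
      list(n_tested = nrow(r), n_enriched = nrow(sig),
           top_terms = utils::head(sig$term_id, 10))
    })
    if (!is.null(enrichment$term_proportions)) {
      report$term_proportions <- as.list(enrichment$term_proportions)
    }
  }
  class(report) <- "homoeolog_report"
  check_report_consistency(report)
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(unclass(config), function(x)
    if (is.null(x)) NA else x), out("config.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(report)
}

# Every reported percentage must be recomputable from the reported counts.
check_report_consistency <- function(report) {
  ct <- report$contingency
  if (ct$total > 0) {
    stopifnot(
      ct$total == sum(ct$counts),
      ct$pct_bbh_syntenic ==
        round_half_up(100 * ct$counts[["BBH_syntenic"]] / ct$total, 1),
      ct$pct_nonbbh_nonsyntenic ==
        round_half_up(100 * ct$counts[["nonBBH_nonsyntenic"]] / ct$total, 1),
      ct$pct_not_bbh_syntenic ==
        round_half_up(100 * (ct$total - ct$counts[["BBH_syntenic"]]) / ct$total, 1))
  }
  ov <- report$overlap
  stopifnot(
    ov$n_only1 == ov$n_method1 - ov$n_shared,
    ov$n_only2 == ov$n_method2 - ov$n_shared,
    ov$n_only2 == ov$only2_coverage_fail + ov$only2_paralog_flagged + ov$only2_residual,
    ov$pct_of_method1 == round_half_up(100 * ov$n_shared / max(1L, ov$n_method1), 1),
    ov$pct_of_method2 == round_half_up(100 * ov$n_shared / max(1L, ov$n_method2), 1))
  invisible(TRUE)
}

#' @export
print.homoeolog_report <- function(x, ...) {
  cat("Homoeolog pipeline report\n")
  cat(sprintf("  comprehensive pairs: %d (BBH: %d); scored: %d, excluded: %d\n",
              x$counts$comprehensive_pairs, x$counts$bbh_pairs,
              x$counts$scored_pairs, x$counts$excluded_pairs))
  ct <- x$contingency
  for (l in names(ct$counts)) cat(sprintf("  %-20s %6d\n", l, ct$counts[[l]]))
  cat(sprintf("  BBH & syntenic: %.1f%%; not BBH & syntenic: %.1f%%; both non: %.1f%%\n",
              ct$pct_bbh_syntenic, ct$pct_not_bbh_syntenic,
              ct$pct_nonbbh_nonsyntenic))
  invisible(x)
}

#' One-command synthetic demo
#'
#' Simulates a default synthetic allopolyploid (with expression and a planted
#' GO enrichment), writes the fixtures, and runs the full pipeline on them.
#'
#' @param seed integer seed for all generators
#' @param dir working directory for fixtures and outputs
#' @param sim a [sim_config()] (its own seed is overridden by `seed`)
#' @param enrichment_odds odds multiplier for the planted GO term
#' @return list: `report`, `dataset`, `go`, `dir`, `config`
#' @export
demo_pipeline <- function(seed = 1L, dir = tempfile("homoeolog_demo"),
                          sim = sim_config(), enrichment_odds = 20) {
  sim$seed <- as.integer(seed)
  dataset <- simulate_allopolyploid(sim)
  expr <- simulate_expression(dataset, seed = seed + 1L)
  go <- simulate_go(dataset, enrichment_odds = enrichment_odds, seed = seed + 2L)
  fdir <- file.path(dir, "fixtures")
  write_fixtures(dataset, fdir, expression = expr, go = go)
  cfg <- pipeline_config(
    fasta_a = file.path(fdir, "proteins_A.fasta"),
    fasta_d = file.path(fdir, "proteins_D.fasta"),
    gene_order = file.path(fdir, "gene_order.tsv"),
    out_dir = file.path(dir, "out"),
    outgroup_fasta = if (!is.null(dataset$outgroup_proteins))
      file.path(fdir, "outgroup.fasta"),
    expression = file.path(fdir, "expression.tsv"),
    design = file.path(fdir, "design.tsv"),
    obo = file.path(fdir, "go.obo"),
    annotations = file.path(fdir, "annotations.tsv"),
    report_terms = go$planted_term,
    seed = as.integer(seed))
  report <- run_pipeline(cfg)
  list(report = report, dataset = dataset, go = go, dir = dir, config = cfg)
}
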