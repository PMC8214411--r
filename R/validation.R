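# Truth-recovery and calibration experiments on the synthetic generator.

#' Parameter-recovery statistics for one synthetic run
#'
#' Runs the full pipeline on a synthetic dataset ([demo_pipeline()]) and
#' scores inference against the generator's truth table: how many surviving
#' planted dispersed duplicates are classified nonsyntenic, how many interior
#' ancestral 1:1 pairs come out BBH & syntenic, how many planted hidden
#' paralogs the witness filter flags, and the Bonferroni-corrected p of the
#' planted GO term in its planted category. "Interior" means both genes at
#' least `half_window` positions from their scaffold ends, so both windows
#' are full.
#'
#' @param seed integer seed
#' @param sim a [sim_config()]
#' @param enrichment_odds odds of the planted GO enrichment
#' @param half_window window half-size used for the interior definition
#' @return list of counts and rates (see details in the field names)
#' @export
recovery_stats <- function(seed = 1L, sim = sim_config(), enrichment_odds = 20,
                           half_window = 5) {
  d <- demo_pipeline(seed = seed, sim = sim, enrichment_odds = enrichment_odds)
  on.exit(unlink(d$dir, recursive = TRUE), add = TRUE)
  truth <- d$dataset$truth
  pairs <- read_tsv(file.path(d$dir, "out", "pairs.tsv"))
  flagged_path <- file.path(d$dir, "out", "flagged_pairs.tsv")
  flagged <- if (file.exists(flagged_path)) read_tsv(flagged_path) else
    data.frame(gene_a = character(0), gene_d = character(0))

  tk <- pair_key(truth$gene_a, truth$gene_d)
  retained_k <- pair_key(pairs$gene_a, pairs$gene_d)
  flagged_k <- pair_key(flagged$gene_a, flagged$gene_d)
  cat_of <- stats::setNames(pairs$category, retained_k)

  disp <- tk[truth$event_class == "dispersed_dup"]
  disp_surv <- disp[disp %in% retained_k]
  disp_nonsyn <- sum(cat_of[disp_surv] %in% c("nonBBH_nonsyntenic",
                                              "BBH_nonsyntenic"))

  # interior ancestral pairs: both windows full
  g <- d$dataset$genes
  scaf_len <- stats::setNames(as.integer(table(g$scaffold)), names(table(g$scaffold)))
  pos <- stats::setNames(g$position, g$gene_id)
  scaf <- stats::setNames(g$scaffold, g$gene_id)
  interior <- function(id) {
    p <- pos[[id]]; L <- scaf_len[[scaf[[id]]]]
    p >= half_window && p <= L - 1L - half_window
  }
  anc <- truth[truth$event_class == "ancestral_1to1", , drop = FALSE]
  anc_int <- anc[vapply(anc$gene_a, interior, logical(1)) &
                 vapply(anc$gene_d, interior, logical(1)), , drop = FALSE]
  anc_k <- pair_key(anc_int$gene_a, anc_int$gene_d)
  anc_ok <- sum(!is.na(cat_of[anc_k]) & cat_of[anc_k] == "BBH_syntenic")

  hid <- tk[truth$event_class == "hidden_paralog"]
  hid_cand <- hid[hid %in% c(retained_k, flagged_k)]
  hid_flagged <- sum(hid_cand %in% flagged_k)

  enr_path <- file.path(d$dir, "out", "enrichment_nonBBH_nonsyntenic.tsv")
  planted_p <- NA_real_
  if (file.exists(enr_path)) {
    enr <- read_tsv(enr_path)
    row <- enr[enr$term_id == d$go$planted_term, , drop = FALSE]
    if (nrow(row) == 1L) planted_p <- row$p_bonferroni
  }

  list(seed = seed,
       dispersed_surviving = length(disp_surv),
       dispersed_nonsyntenic = disp_nonsyn,
       ancestral_interior = nrow(anc_int),
       ancestral_bbh_syntenic = anc_ok,
       hidden_candidates = length(hid_cand),
       hidden_flagged = hid_flagged,
       planted_term_p_bonferroni = planted_p,
       report = d$report)
}

#' Null calibration of the enrichment test
#'
#' With enrichment odds 1 nothing is planted, so the raw Fisher p-values over
#' leaf terms should be approximately uniform: about 5% of tested leaf terms
#' reach raw p < 0.05 (slightly fewer, as the exact test is discretely
#' conservative). Pools several independent annotation draws over one
#' simulated genome; categories come from the generator's truth labels so no
#' alignment is needed.
#'
#' @param seed integer seed
#' @param n_replicates independent annotation draws to pool
#' @param sim a [sim_config()]
#' @param study_category truth category used as the study set
#' @return list: `fraction_p_lt_05`, `n_tests`
#' @export
null_calibration <- function(seed = 1L, n_replicates = 10,
                             sim = sim_config(),
                             study_category = "nonBBH_nonsyntenic") {
  sim$seed <- as.integer(seed)
  ds <- simulate_allopolyploid(sim)
  truth <- ds$truth[ds$truth$expected_category != "excluded", , drop = FALSE]
  population <- unique(c(truth$gene_a, truth$gene_d))
  study <- unique(c(truth$gene_a[truth$expected_category == study_category],
                    truth$gene_d[truth$expected_category == study_category]))
  n_sig <- 0L; n_tot <- 0L
  for (r in seq_len(n_replicates)) {
    go <- simulate_go(ds, enrichment_odds = 1, seed = seed * 1000L + r)
    ann <- propagate_annotations(go$annotations, go$dag)
    res <- fisher_enrichment(study, population, ann)
    res <- res[res$term_id %in% go$leaf_terms, , drop = FALSE]
    n_sig <- n_sig + sum(res$p_value < 0.05)
    n_tot <- n_tot + nrow(res)
  }
  list(fraction_p_lt_05 = n_sig / n_tot, n_tests = n_tot)
}
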