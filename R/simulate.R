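#' Configuration for the synthetic allopolyploid generator
#'
#' Bundles and validates the parameters of [simulate_allopolyploid()]. The
#' generator emulates an allopolyploid that arose from two progenitor lineages
#' ("A" and "D" subgenomes) which diverged from a common ancestor, with
#' post-divergence tandem and dispersed gene duplication, gene transposition
#' (move without copy), gene loss, and an optional outgroup genome. Hidden
#' paralogs -- the classic pitfall of best-hit homoeolog inference -- are
#' planted as a duplication older than the outgroup split followed by
#' complementary losses in the two subgenomes, with the outgroup retaining
#' both copies.
#'
#' @param n_ancestral_genes number of genes in the common ancestor (>= 4)
#' @param n_scaffolds_per_subgenome number of scaffolds each subgenome's genes
#'   are laid out on
#' @param divergence_distance expected substitutions per 100 residues between
#'   the two subgenome copies of an ancestral gene (PAM-like scale)
#' @param tandem_dup_rate per-gene probability of a post-divergence tandem
#'   duplication (copy inserted adjacent to the parent)
#' @param dispersed_dup_rate per-gene probability of a dispersed duplication
#'   (copy inserted at a uniformly random position on a random scaffold)
#' @param transposition_rate per-gene probability of a transposition (the gene
#'   itself moves to a random position; no copy is made)
#' @param loss_rate per-gene per-subgenome probability of gene loss
#' @param hidden_paralog_rate per-ancestral-gene probability of planting a
#'   hidden-paralog scenario (only realised when `outgroup = TRUE`)
#' @param mean_protein_length,length_dispersion log-normal protein length model
#'   (residues; `length_dispersion` is the sdlog)
#' @param outgroup simulate an outgroup genome retaining duplicate copies?
#' @param outgroup_divergence substitutions per 100 residues between the
#'   ancestor and the outgroup copy of each gene
#' @param dup_divergence extra substitutions per 100 residues between a
#'   duplicate and its parent
#' @param paralog_divergence substitutions per 100 residues between the two
#'   copies of the old duplication behind hidden paralogs; must exceed
#'   `outgroup_divergence` for the witness geometry to hold
#' @param seed integer seed; identical seeds give byte-identical output
#' @return an object of class `sim_config` (a validated list)
#' @export
sim_config <- function(n_ancestral_genes = 500,
                       n_scaffolds_per_subgenome = 5,
                       divergence_distance = 6,
                       tandem_dup_rate = 0.05,
                       dispersed_dup_rate = 0.05,
                       transposition_rate = 0.02,
                       loss_rate = 0.03,
                       hidden_paralog_rate = 0.02,
                       mean_protein_length = 200,
                       length_dispersion = 0.25,
                       outgroup = TRUE,
                       outgroup_divergence = 30,
                       dup_divergence = 2,
                       paralog_divergence = 50,
                       seed = 1L) {
  cfg <- list(n_ancestral_genes = as.integer(n_ancestral_genes),
              n_scaffolds_per_subgenome = as.integer(n_scaffolds_per_subgenome),
              divergence_distance = divergence_distance,
              tandem_dup_rate = tandem_dup_rate,
              dispersed_dup_rate = dispersed_dup_rate,
              transposition_rate = transposition_rate,
              loss_rate = loss_rate,
              hidden_paralog_rate = hidden_paralog_rate,
              mean_protein_length = mean_protein_length,
              length_dispersion = length_dispersion,
              outgroup = isTRUE(outgroup),
              outgroup_divergence = outgroup_divergence,
              dup_divergence = dup_divergence,
              paralog_divergence = paralog_divergence,
              seed = as.integer(seed))
  rates <- c("tandem_dup_rate", "dispersed_dup_rate", "transposition_rate",
             "loss_rate", "hidden_paralog_rate")
  for (r in rates) {
    v <- cfg[[r]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("configuration error: %s must be a single value in [0, 1]", r),
           call. = FALSE)
    }
  }
  if (is.na(cfg$n_ancestral_genes) || cfg$n_ancestral_genes < 4L) {
    stop("configuration error: n_ancestral_genes must be >= 4", call. = FALSE)
  }
  if (cfg$n_scaffolds_per_subgenome < 1L) {
    stop("configuration error: n_scaffolds_per_subgenome must be >= 1", call. = FALSE)
  }
  if (cfg$divergence_distance < 0 || cfg$outgroup_divergence < 0 ||
      cfg$dup_divergence < 0 || cfg$paralog_divergence < 0) {
    stop("configuration error: divergence parameters must be non-negative", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Per-site substitution with expected `rate` substitutions per site
# (Poisson-style saturation: a site changes with probability 1 - exp(-rate),
# to a uniformly chosen different residue).
mutate_protein <- function(chars, rate) {
  if (rate <= 0) return(chars)
  p <- 1 - exp(-rate)
  hit <- stats::runif(length(chars)) < p
  n_hit <- sum(hit)
  if (n_hit > 0L) {
    cur <- chars[hit]
    new <- AA_ALPHABET20[sample.int(19L, n_hit, replace = TRUE)]
    # shift collisions (sampling from the 19 *other* residues)
    idx <- match(cur, AA_ALPHABET20)
    new_idx <- match(new, AA_ALPHABET20)
    new_idx <- ifelse(new_idx >= idx, new_idx + 1L, new_idx)
    new_idx[new_idx > 20L] <- new_idx[new_idx > 20L] - 20L
    chars[hit] <- AA_ALPHABET20[new_idx]
  }
  chars
}

random_protein <- function(len) {
  c("M", AA_ALPHABET20[sample.int(20L, len - 1L, replace = TRUE)])
}

#' Simulate a truth-labelled allopolyploid dataset
#'
#' Generates two subgenomes descended from a common set of ancestral genes,
#' applies the evolutionary events configured in [sim_config()], and logs
#' every surviving cross-subgenome homologous relation as a truth record with
#' its event class and the BBH-by-synteny category the analysis is expected to
#' assign it. Tandem duplicates are inserted next to their parent (synteny
#' preserved); dispersed duplicates and transposed genes go to uniformly
#' random positions (synteny destroyed). Expected categories are best-effort
#' labels: a duplicate can legitimately land inside a syntenic block.
#'
#' @param config a [sim_config()] object
#' @return an object of class `homoeolog_sim`: a list with elements
#'   `genes` (data.frame: gene_id, subgenome, scaffold, position,
#'   protein_length), `proteins` (named character vector of amino-acid
#'   sequences), `truth` (data.frame: gene_a, gene_d, event_class,
#'   expected_category), `events` (generator event log), `outgroup_genes` and
#'   `outgroup_proteins` (or NULL), and `config`
#' @export
simulate_allopolyploid <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, as.list(config))
  set.seed(config$seed)
  n <- config$n_ancestral_genes

  lens <- pmax(50L, round(stats::rlnorm(n,
    meanlog = log(config$mean_protein_length) - config$length_dispersion^2 / 2,
    sdlog = config$length_dispersion)))
  anc <- lapply(lens, random_protein)

  # hidden paralogs: old duplication (copy Y), outgroup will retain both
  hidden <- if (config$outgroup && config$hidden_paralog_rate > 0) {
    which(stats::runif(n) < config$hidden_paralog_rate)
  } else integer(0)
  anc_y <- vector("list", n)
  for (i in hidden) anc_y[[i]] <- mutate_protein(anc[[i]], config$paralog_divergence / 100)

  scaffold_of <- ceiling(seq_len(n) * config$n_scaffolds_per_subgenome / n)
  branch_rate <- config$divergence_distance / 200  # per-site, per subgenome branch

  events <- list()
  log_event <- function(subgenome, event, gene, parent = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      subgenome = subgenome, event = event, gene = gene, parent = parent,
      stringsAsFactors = FALSE)
  }

  build_subgenome <- function(sub) {
    ids <- sprintf("%s_g%04d", sub, seq_len(n))
    seqs <- vector("list", n)
    for (i in seq_len(n)) {
      base <- if (i %in% hidden && sub == "D") anc_y[[i]] else anc[[i]]
      seqs[[i]] <- mutate_protein(base, branch_rate)
    }
    names(seqs) <- ids

    lost <- stats::runif(n) < config$loss_rate
    for (i in which(lost)) log_event(sub, "loss", ids[i])

    # per-scaffold ordered id lists, ancestral order, losses removed
    scaffolds <- lapply(seq_len(config$n_scaffolds_per_subgenome), function(s) {
      ids[scaffold_of == s & !lost]
    })
    surv <- ids[!lost]
    anc_of <- stats::setNames(seq_len(n), ids)  # ancestral family index

    insert_at <- function(vec, x, pos) append(vec, x, after = pos)

    # tandem duplications: child adjacent to parent
    for (g in surv[stats::runif(length(surv)) < config$tandem_dup_rate]) {
      child <- paste0(g, ".t1")
      seqs[[child]] <- mutate_protein(seqs[[g]], config$dup_divergence / 100)
      anc_of[child] <- anc_of[[g]]
      s <- which(vapply(scaffolds, function(v) g %in% v, logical(1)))[1]
      scaffolds[[s]] <- insert_at(scaffolds[[s]], child, match(g, scaffolds[[s]]))
      log_event(sub, "tandem_dup", child, g)
    }
    # dispersed duplications: child at a random position on a random scaffold
    for (g in surv[stats::runif(length(surv)) < config$dispersed_dup_rate]) {
      child <- paste0(g, ".d1")
      seqs[[child]] <- mutate_protein(seqs[[g]], config$dup_divergence / 100)
      anc_of[child] <- anc_of[[g]]
      s <- sample.int(length(scaffolds), 1L)
      scaffolds[[s]] <- insert_at(scaffolds[[s]], child,
                                  sample.int(length(scaffolds[[s]]) + 1L, 1L) - 1L)
      log_event(sub, "dispersed_dup", child, g)
    }
    # transpositions: cut and paste the gene itself
    moved <- character(0)
    for (g in surv[stats::runif(length(surv)) < config$transposition_rate]) {
      s_old <- which(vapply(scaffolds, function(v) g %in% v, logical(1)))[1]
      scaffolds[[s_old]] <- setdiff(scaffolds[[s_old]], g)
      s <- sample.int(length(scaffolds), 1L)
      scaffolds[[s]] <- insert_at(scaffolds[[s]], g,
                                  sample.int(length(scaffolds[[s]]) + 1L, 1L) - 1L)
      moved <- c(moved, g)
      log_event(sub, "transposition", g)
    }

    all_ids <- unlist(scaffolds, use.names = FALSE)
    genes <- data.frame(
      gene_id = all_ids,
      subgenome = sub,
      scaffold = rep(sprintf("%s_s%d", sub, seq_along(scaffolds)),
                     vapply(scaffolds, length, integer(1))),
      position = unlist(lapply(scaffolds, function(v) seq_along(v) - 1L),
                        use.names = FALSE),
      stringsAsFactors = FALSE)
    list(genes = genes, seqs = seqs[all_ids], anc_of = anc_of[all_ids],
         moved = moved)
  }

  A <- build_subgenome("A")
  D <- build_subgenome("D")

  genes <- rbind(A$genes, D$genes)
  proteins <- vapply(c(A$seqs, D$seqs), paste0, character(1), collapse = "")
  genes$protein_length <- nchar(proteins)[match(genes$gene_id, names(proteins))]

  gene_kind <- function(id) {
    if (endsWith(id, ".d1")) "dispersed" else if (endsWith(id, ".t1")) "tandem" else "orig"
  }
  truth <- list()
  for (i in seq_len(n)) {
    fam_a <- names(A$anc_of)[A$anc_of == i]
    fam_d <- names(D$anc_of)[D$anc_of == i]
    if (length(fam_a) == 0L || length(fam_d) == 0L) next
    for (ga in fam_a) for (gd in fam_d) {
      ka <- gene_kind(ga); kd <- gene_kind(gd)
      cls <- if (ka == "dispersed" || kd == "dispersed") "dispersed_dup"
        else if (ka == "tandem" || kd == "tandem") "tandem_dup"
        else if (i %in% hidden) "hidden_paralog"
        else if (ga %in% A$moved || gd %in% D$moved) "transposed"
        else "ancestral_1to1"
      truth[[length(truth) + 1L]] <- data.frame(
        gene_a = ga, gene_d = gd, event_class = cls,
        expected_category = switch(cls,
          ancestral_1to1 = "BBH_syntenic",
          tandem_dup     = "nonBBH_syntenic",
          dispersed_dup  = "nonBBH_nonsyntenic",
          transposed     = "BBH_nonsyntenic",
          hidden_paralog = "excluded"),
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(gene_a = character(0), gene_d = character(0),
               event_class = character(0), expected_category = character(0))

  out_genes <- NULL; out_proteins <- NULL
  if (config$outgroup) {
    og_rate <- config$outgroup_divergence / 100
    ids <- sprintf("O_g%04d", seq_len(n))
    oseqs <- lapply(seq_len(n), function(i) mutate_protein(anc[[i]], og_rate))
    names(oseqs) <- ids
    for (i in hidden) {
      oseqs[[sprintf("O_g%04db", i)]] <- mutate_protein(anc_y[[i]], og_rate)
    }
    out_proteins <- vapply(oseqs, paste0, character(1), collapse = "")
    out_genes <- data.frame(
      gene_id = names(oseqs), subgenome = "none", scaffold = "O_s1",
      position = seq_along(oseqs) - 1L,
      protein_length = nchar(out_proteins), stringsAsFactors = FALSE)
  }

  events <- if (length(events) > 0L) do.call(rbind, events) else
    data.frame(subgenome = character(0), event = character(0),
               gene = character(0), parent = character(0))

  structure(list(genes = genes, proteins = proteins, truth = truth,
                 events = events, outgroup_genes = out_genes,
                 outgroup_proteins = out_proteins, config = config),
            class = "homoeolog_sim")
}

#' @export
print.homoeolog_sim <- function(x, ...) {
  cat("Synthetic allopolyploid dataset\n")
  cat(sprintf("  genes: %d (A: %d, D: %d)%s\n", nrow(x$genes),
              sum(x$genes$subgenome == "A"), sum(x$genes$subgenome == "D"),
              if (!is.null(x$outgroup_genes))
                sprintf(", outgroup: %d", nrow(x$outgroup_genes)) else ""))
  cat(sprintf("  truth relations: %d\n", nrow(x$truth)))
  if (nrow(x$truth) > 0) {
    tb <- table(x$truth$event_class)
    cat(paste0("    ", names(tb), ": ", tb, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Expression design: conditions, time points and noise model
#'
#' Default design mirrors a 12-tissue unstressed survey in which five tissues
#' carry multiple time-point samples (fiber 4, cotyledon 5, root 5, ovule 8,
#' seed 3) and the rest one sample each, 32 samples in total. TPM values are
#' log-normal with a per-gene effect; dropout silences a gene in a whole
#' condition (all its time points).
#'
#' @param conditions character vector of condition (tissue) names
#' @param timepoints named integer vector: samples per condition (>= 1);
#'   conditions absent from it get a single sample
#' @param log_mean,log_sd log-scale mean and total sd of TPM
#' @param dropout probability that a gene x condition is silenced (TPM 0)
#' @return object of class `expression_design` with a `samples` data.frame
#'   (sample, condition)
#' @export
expression_design <- function(conditions = c("leaves", "seed", "cotyledon", "stem",
                                             "petals", "roots", "torus", "stamen",
                                             "pistil", "calycle", "ovule", "fiber"),
                              timepoints = c(fiber = 4L, cotyledon = 5L,
                                             roots = 5L, ovule = 8L, seed = 3L),
                              log_mean = log(8), log_sd = 1.5, dropout = 0.25) {
  if (anyDuplicated(conditions)) stop("condition names must be unique", call. = FALSE)
  n_samp <- stats::setNames(rep(1L, length(conditions)), conditions)
  n_samp[names(timepoints)] <- as.integer(timepoints)
  if (any(n_samp < 1L)) stop("every condition needs >= 1 sample", call. = FALSE)
  samples <- do.call(rbind, lapply(conditions, function(cn) {
    k <- n_samp[[cn]]
    data.frame(sample = if (k == 1L) cn else sprintf("%s_t%d", cn, seq_len(k)),
               condition = cn, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(samples$sample)) stop("sample labels must be unique", call. = FALSE)
  structure(list(conditions = conditions, samples = samples,
                 log_mean = log_mean, log_sd = log_sd, dropout = dropout),
            class = "expression_design")
}

#' Simulate a sample-level TPM table
#'
#' @param dataset a `homoeolog_sim` object (or anything with a `genes`
#'   data.frame); expression is generated for its subgenome genes
#' @param design an [expression_design()]
#' @param seed integer seed
#' @return numeric matrix genes x samples, with a `"design"` attribute
#' @export
simulate_expression <- function(dataset, design = expression_design(), seed = 1L) {
  genes <- dataset$genes$gene_id
  if (length(genes) == 0L) stop("dataset contains no genes", call. = FALSE)
  set.seed(seed)
  ns <- nrow(design$samples)
  sd_gene <- design$log_sd * sqrt(0.5)
  sd_resid <- design$log_sd * sqrt(0.5)
  effect <- stats::rnorm(length(genes), 0, sd_gene)
  m <- exp(matrix(stats::rnorm(length(genes) * ns, design$log_mean + effect, sd_resid),
                  nrow = length(genes), ncol = ns))
  dimnames(m) <- list(genes, design$samples$sample)
  if (design$dropout > 0) {
    for (cn in design$conditions) {
      cols <- design$samples$sample[design$samples$condition == cn]
      drop <- stats::runif(length(genes)) < design$dropout
      m[drop, cols] <- 0
    }
  }
  attr(m, "design") <- design$samples
  m
}

#' Simulate a GO DAG and gene annotations with a planted enrichment
#'
#' Builds a small rooted is_a DAG (one root, a layer of intermediate terms,
#' the rest leaves) and annotates genes to leaf terms independently with
#' per-term baseline probabilities. Genes whose truth category equals
#' `planted_category` receive `planted_term` with odds multiplied by
#' `enrichment_odds`; `enrichment_odds = 1` is the null.
#'
#' @param dataset a `homoeolog_sim` object with a truth table
#' @param n_terms total number of terms including root and intermediates
#' @param planted_term term id to enrich (default: the first leaf)
#' @param planted_category one of the four BBH-by-synteny labels
#' @param enrichment_odds odds multiplier (>= 1) for the planted term in the
#'   planted category
#' @param seed integer seed
#' @param baseline_range range of per-leaf baseline annotation probabilities
#' @return list: `dag` (a `go_dag`), `annotations` (data.frame gene_id,
#'   term_id; direct, unpropagated), `planted_term`, `leaf_terms`
#' @export
simulate_go <- function(dataset, n_terms = 40, planted_term = NULL,
                        planted_category = "nonBBH_nonsyntenic",
                        enrichment_odds = 20, seed = 1L,
                        baseline_range = c(0.1, 0.4)) {
  if (!planted_category %in% CATEGORY_LABELS) {
    stop("planted_category must be one of: ", paste(CATEGORY_LABELS, collapse = ", "),
         call. = FALSE)
  }
  if (enrichment_odds < 1) stop("enrichment_odds must be >= 1", call. = FALSE)
  if (n_terms < 4) stop("need at least 4 terms", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  root <- ids[1]
  n_mid <- max(2L, round(n_terms * 0.12))
  mid <- ids[1 + seq_len(n_mid)]
  leaves <- ids[-seq_len(1 + n_mid)]
  parents <- c(stats::setNames(rep(list(character(0)), 1), root),
               stats::setNames(rep(list(root), n_mid), mid),
               stats::setNames(as.list(mid[sample.int(n_mid, length(leaves),
                                                      replace = TRUE)]), leaves))
  dag <- go_dag(data.frame(id = ids,
                           name = c("biological_process",
                                    sprintf("process_%d", seq_len(n_mid)),
                                    sprintf("leaf_process_%d", seq_along(leaves))),
                           namespace = "biological_process",
                           stringsAsFactors = FALSE),
                parents)
  if (is.null(planted_term)) planted_term <- leaves[1]
  if (!planted_term %in% ids) stop("planted_term not in DAG", call. = FALSE)

  genes <- dataset$genes$gene_id
  planted_genes <- unique(c(
    dataset$truth$gene_a[dataset$truth$expected_category == planted_category],
    dataset$truth$gene_d[dataset$truth$expected_category == planted_category]))
  p <- stats::runif(length(leaves), baseline_range[1], baseline_range[2])
  names(p) <- leaves

  ann <- list()
  for (t in leaves) {
    pt <- rep(p[[t]], length(genes))
    if (t == planted_term && enrichment_odds > 1) {
      boost <- genes %in% planted_genes
      pt[boost] <- enrichment_odds * pt[boost] /
        (1 - pt[boost] + enrichment_odds * pt[boost])
    }
    hit <- genes[stats::runif(length(genes)) < pt]
    if (length(hit) > 0L) {
      ann[[t]] <- data.frame(gene_id = hit, term_id = t, stringsAsFactors = FALSE)
    }
  }
  annotations <- if (length(ann) > 0L) do.call(rbind, ann) else
    data.frame(gene_id = character(0), term_id = character(0))
  rownames(annotations) <- NULL
  list(dag = dag, annotations = annotations,
       planted_term = planted_term, leaf_terms = leaves)
}
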