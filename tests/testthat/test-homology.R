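test_that("BBH extraction on a 2x2 score matrix follows the definition", {
  M <- matrix(c(5, 1, 1, 4), 2, byrow = TRUE,
              dimnames = list(c("a1", "a2"), c("d1", "d2")))
  b <- infer_bbh(matches_from_matrix(M))
  expect_setequal(paste(b$gene_a, b$gene_d), c("a1 d1", "a2 d2"))
})

test_that("a one-way best hit is not a BBH", {
  # a1's best is d1, but d1's best is a2
  M <- matrix(c(5, 1, 9, 2), 2, byrow = TRUE,
              dimnames = list(c("a1", "a2"), c("d1", "d2")))
  b <- infer_bbh(matches_from_matrix(M))
  expect_false("a1" %in% b$gene_a)
  expect_equal(paste(b$gene_a, b$gene_d), "a2 d1")
})

test_that("BBH equals the brute-force reciprocal-argmax oracle on random matrices", {
  set.seed(88)
  for (k in 1:10) {
    M <- matrix(round(runif(64, 1, 100), 1), 8,
                dimnames = list(paste0("a", 1:8), paste0("d", 1:8)))
    b <- infer_bbh(matches_from_matrix(M))
    b <- b[order(b$gene_a), ]
    o <- bbh_oracle(M)
    expect_equal(b$gene_a, o$gene_a)
    expect_equal(b$gene_d, o$gene_d)
  }
})

test_that("the BBH set is a matching and is symmetric in the two sides", {
  set.seed(12)
  M <- matrix(sample(1:50, 72, replace = TRUE), 8, 9,
              dimnames = list(paste0("a", 1:8), paste0("d", 1:9)))
  b <- infer_bbh(matches_from_matrix(M))
  expect_equal(anyDuplicated(b$gene_a), 0L)
  expect_equal(anyDuplicated(b$gene_d), 0L)
  # swapping which side is queries vs subjects must not change the pair set
  bt <- infer_bbh(matches_from_matrix(t(M)))
  expect_setequal(paste(b$gene_a, b$gene_d), paste(bt$gene_a, bt$gene_d))
})

test_that("tolerant inference with epsilon 0 reduces to BBH when ties are absent", {
  set.seed(41)
  for (k in 1:6) {
    M <- matrix(round(runif(49, 1, 100), 2), 7,
                dimnames = list(paste0("a", 1:7), paste0("d", 1:7)))
    m <- matches_from_matrix(M)
    tol <- infer_homoeologs_tolerant(m, epsilon = 0)
    bbh <- infer_bbh(m)
    expect_setequal(paste(tol$gene_a, tol$gene_d), paste(bbh$gene_a, bbh$gene_d))
  }
})

test_that("a recent duplicate within the tolerance gives a 1:2 relation", {
  M <- matrix(c(10, 9.5), 1, dimnames = list("a1", c("d1", "d2")))
  tol <- infer_homoeologs_tolerant(matches_from_matrix(M), epsilon = 0.1)
  expect_equal(nrow(tol), 2)
  expect_setequal(tol$gene_d, c("d1", "d2"))
  strict <- infer_homoeologs_tolerant(matches_from_matrix(M), epsilon = 0.01)
  expect_equal(strict$gene_d, "d1")
})

test_that("coverage-failing matches never enter the tolerant set", {
  M <- matrix(c(10, 8, 7, 9), 2, byrow = TRUE,
              dimnames = list(c("a1", "a2"), c("d1", "d2")))
  m <- matches_from_matrix(M, coverage = 0.5)  # all fail the 0.6 default
  expect_equal(nrow(infer_homoeologs_tolerant(m)), 0)
  expect_equal(nrow(infer_bbh(m)), 2)  # BBH itself has no coverage filter
  expect_error(infer_homoeologs_tolerant(m, epsilon = -0.1), ">= 0")
})

test_that("coverage-passing BBH pairs are a subset of the tolerant set", {
  set.seed(99)
  for (k in 1:5) {
    M <- matrix(round(runif(36, 1, 100), 1), 6,
                dimnames = list(paste0("a", 1:6), paste0("d", 1:6)))
    m <- matches_from_matrix(M)
    bbh_k <- with(infer_bbh(m), paste(gene_a, gene_d))
    for (eps in c(0, 0.05, 0.2)) {
      tol_k <- with(infer_homoeologs_tolerant(m, epsilon = eps),
                    paste(gene_a, gene_d))
      expect_true(all(bbh_k %in% tol_k), label = sprintf("eps=%g", eps))
    }
  }
})

test_that("tolerant genes with exactly one relation on both sides form BBH pairs", {
  # "all 1:1 pairs are BBHs, but not all BBHs are 1:1". With a positive
  # tolerance this holds on sequence-derived scores (near-ties arise only
  # among recent duplicates), and exactly at epsilon 0 on arbitrary scores.
  one_to_one_in_bbh <- function(m, epsilon) {
    tol <- infer_homoeologs_tolerant(m, epsilon = epsilon)
    bbh_k <- with(infer_bbh(m), paste(gene_a, gene_d))
    deg <- table(c(tol$gene_a, tol$gene_d))
    one <- tol[deg[tol$gene_a] == 1 & deg[tol$gene_d] == 1, ]
    all(paste(one$gene_a, one$gene_d) %in% bbh_k)
  }
  set.seed(7)
  for (k in 1:5) {
    M <- matrix(round(runif(64, 1, 100), 1), 8,
                dimnames = list(paste0("a", 1:8), paste0("d", 1:8)))
    expect_true(one_to_one_in_bbh(matches_from_matrix(M), epsilon = 0))
  }
  ds <- simulate_allopolyploid(sim_config(n_ancestral_genes = 60,
                                          outgroup = FALSE, seed = 23))
  g <- ds$genes
  m <- all_vs_all(ds$proteins[g$gene_id[g$subgenome == "A"]],
                  ds$proteins[g$gene_id[g$subgenome == "D"]], engine = "blast")
  expect_true(one_to_one_in_bbh(m, epsilon = 0.05))
})

test_that("the witness filter passes everything through without outgroup data", {
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_d = c("d1", "d2"))
  w <- witness_filter(pairs, NULL)
  expect_identical(w$retained, pairs)
  expect_equal(nrow(w$flagged), 0)
})

test_that("the witness filter flags a constructed hidden paralog and keeps an ortholog", {
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_d = c("d1", "d2"),
                      stringsAsFactors = FALSE)
  og <- function(q, s, sc) data.frame(query = q, subject = s, score = sc,
                                      percent_identity = 90, query_coverage = 1,
                                      subject_coverage = 1, evalue = NA_real_,
                                      coverage_pass = TRUE, stringsAsFactors = FALSE)
  out_m <- list(
    # a1/d1: distinct witnesses o1a, o1b that are distant from each other
    # a2/d2: both point at the same outgroup gene o2
    a = rbind(og("a1", "o1a", 100), og("a1", "o1b", 40), og("a2", "o2", 90)),
    d = rbind(og("d1", "o1b", 95), og("d1", "o1a", 35), og("d2", "o2", 85)),
    outgroup = og("o1a", "o1b", 30))
  w <- witness_filter(pairs, out_m)
  expect_equal(w$flagged$gene_a, "a1")
  expect_equal(w$flagged$witness_a, "o1a")
  expect_equal(w$flagged$witness_d, "o1b")
  expect_equal(w$retained$gene_a, "a2")
  # witnesses closer to each other than to the pair -> not flagged
  out_m$outgroup <- og("o1a", "o1b", 120)
  expect_equal(nrow(witness_filter(pairs, out_m)$flagged), 0)
})

test_that("planted hidden paralogs from the generator are flagged end to end", {
  cfg <- sim_config(n_ancestral_genes = 60, n_scaffolds_per_subgenome = 2,
                    tandem_dup_rate = 0, dispersed_dup_rate = 0,
                    transposition_rate = 0, loss_rate = 0,
                    hidden_paralog_rate = 0.1, seed = 17)
  ds <- simulate_allopolyploid(cfg)
  g <- ds$genes
  pa <- ds$proteins[g$gene_id[g$subgenome == "A"]]
  pd <- ds$proteins[g$gene_id[g$subgenome == "D"]]
  og <- ds$outgroup_proteins
  m <- rbind(all_vs_all(pa, pd, engine = "blast"),
             all_vs_all(pd, pa, engine = "blast"))
  tol <- infer_homoeologs_tolerant(m)
  oo <- all_vs_all(og, og, min_coverage = 0, engine = "blast")
  w <- witness_filter(tol, list(
    a = all_vs_all(pa, og, min_coverage = 0, engine = "blast"),
    d = all_vs_all(pd, og, min_coverage = 0, engine = "blast"),
    outgroup = oo[oo$query != oo$subject, ]))
  hid <- ds$truth[ds$truth$event_class == "hidden_paralog", ]
  expect_gt(nrow(hid), 0)
  flagged_k <- paste(w$flagged$gene_a, w$flagged$gene_d)
  expect_true(all(paste(hid$gene_a, hid$gene_d) %in% flagged_k))
  # ancestral 1:1 pairs are retained, not flagged
  anc <- ds$truth[ds$truth$event_class == "ancestral_1to1", ]
  expect_true(mean(paste(anc$gene_a, anc$gene_d) %in%
                   paste(w$retained$gene_a, w$retained$gene_d)) > 0.95)
})

test_that("PAM estimate follows the stated correction and its domain", {
  expect_equal(estimate_pam_distance(100), 0)
  p <- 0.30
  expect_equal(estimate_pam_distance(70), -100 * log(1 - p - 0.2 * p^2))
  # strictly increasing in p on a grid
  ident <- seq(99, 16, by = -1)
  d <- estimate_pam_distance(ident)
  expect_true(all(diff(d) > 0))
  expect_error(estimate_pam_distance(14), "saturates")
  expect_error(estimate_pam_distance(0), "\\(0, 100\\]")
  expect_error(estimate_pam_distance(101), "\\(0, 100\\]")
})
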