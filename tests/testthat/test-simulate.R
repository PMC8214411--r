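test_that("configuration is validated", {
  expect_error(sim_config(tandem_dup_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(loss_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(n_ancestral_genes = 3), ">= 4")
})

zero_cfg <- function(n = 40, ...) {
  sim_config(n_ancestral_genes = n, n_scaffolds_per_subgenome = 2,
             divergence_distance = 0, tandem_dup_rate = 0,
             dispersed_dup_rate = 0, transposition_rate = 0, loss_rate = 0,
             hidden_paralog_rate = 0, seed = 42, ...)
}

test_that("with all rates and divergence zero, subgenomes are identical 1:1 copies", {
  ds <- simulate_allopolyploid(zero_cfg())
  expect_equal(nrow(ds$truth), 40)
  expect_true(all(ds$truth$event_class == "ancestral_1to1"))
  # identical counterpart sequences
  a_seq <- ds$proteins[ds$truth$gene_a]
  d_seq <- ds$proteins[ds$truth$gene_d]
  expect_equal(unname(a_seq), unname(d_seq))
  # ancestral order preserved on both subgenomes
  g <- ds$genes
  expect_equal(g$position[g$subgenome == "A"], g$position[g$subgenome == "D"])
})

test_that("a fixed seed reproduces byte-identical fixtures", {
  cfg <- sim_config(n_ancestral_genes = 60, seed = 9)
  d1 <- simulate_allopolyploid(cfg)
  d2 <- simulate_allopolyploid(cfg)
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$truth, d2$truth)
  t1 <- tempfile(); t2 <- tempfile()
  write_fixtures(d1, t1); write_fixtures(d2, t2)
  for (f in list.files(t1)) {
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)),
                     label = f)
  }
})

test_that("dispersed duplications match the event log and move away from the parent", {
  cfg <- sim_config(n_ancestral_genes = 500, dispersed_dup_rate = 0.1,
                    tandem_dup_rate = 0, transposition_rate = 0, loss_rate = 0,
                    hidden_paralog_rate = 0, outgroup = FALSE, seed = 31)
  ds <- simulate_allopolyploid(cfg)
  log_disp <- ds$events[ds$events$event == "dispersed_dup", ]
  truth_disp <- ds$truth[ds$truth$event_class == "dispersed_dup", ]
  # oracle from the event log alone: with no losses/tandems/transpositions a
  # family with nA and nD copies contributes nA*nD relations, of which one
  # (original x original) is ancestral; the rest involve a dispersed child
  fam <- sub("\\.d1$", "", sub("^[AD]_", "", c(log_disp$parent)))
  n_extra_a <- table(fam[log_disp$subgenome == "A"])
  n_extra_d <- table(fam[log_disp$subgenome == "D"])
  fams <- union(names(n_extra_a), names(n_extra_d))
  na <- 1 + ifelse(fams %in% names(n_extra_a), n_extra_a[fams], 0)
  nd <- 1 + ifelse(fams %in% names(n_extra_d), n_extra_d[fams], 0)
  expect_equal(nrow(truth_disp), sum(na * nd - 1))
  loc <- ds$genes[match(c(log_disp$gene, log_disp$parent), ds$genes$gene_id), ]
  n <- nrow(log_disp)
  child <- loc[seq_len(n), ]; parent <- loc[n + seq_len(n), ]
  moved <- child$scaffold != parent$scaffold |
    abs(child$position - parent$position) > 1
  expect_gt(mean(moved), 0.95)  # random landing can rarely be adjacent
})

test_that("gene counts per subgenome equal ancestral - losses + duplications", {
  cfg <- sim_config(n_ancestral_genes = 200, seed = 13)
  ds <- simulate_allopolyploid(cfg)
  ev <- ds$events
  for (sub in c("A", "D")) {
    n_obs <- sum(ds$genes$subgenome == sub)
    n_loss <- sum(ev$subgenome == sub & ev$event == "loss")
    n_dup <- sum(ev$subgenome == sub & ev$event %in% c("tandem_dup", "dispersed_dup"))
    expect_equal(n_obs, 200 - n_loss + n_dup)
  }
})

test_that("hidden paralogs only appear with an outgroup and are logged once", {
  ds_no <- simulate_allopolyploid(sim_config(n_ancestral_genes = 80,
                                             outgroup = FALSE, seed = 2,
                                             hidden_paralog_rate = 0.2))
  expect_false("hidden_paralog" %in% ds_no$truth$event_class)
  ds <- simulate_allopolyploid(sim_config(n_ancestral_genes = 80, seed = 2,
                                          hidden_paralog_rate = 0.2,
                                          tandem_dup_rate = 0,
                                          dispersed_dup_rate = 0, loss_rate = 0))
  hid <- ds$truth[ds$truth$event_class == "hidden_paralog", ]
  expect_gt(nrow(hid), 0)
  expect_equal(anyDuplicated(paste(hid$gene_a, hid$gene_d)), 0L)
  # outgroup retains both copies of each hidden duplication
  expect_true(all(paste0(sub("A_", "O_", hid$gene_a), "b") %in%
                  ds$outgroup_genes$gene_id))
})

test_that("truth relations are unique across the table", {
  ds <- simulate_allopolyploid(sim_config(n_ancestral_genes = 150, seed = 3))
  expect_equal(anyDuplicated(paste(ds$truth$gene_a, ds$truth$gene_d)), 0L)
  expect_true(all(startsWith(ds$truth$gene_a, "A_")))
  expect_true(all(startsWith(ds$truth$gene_d, "D_")))
})

test_that("expression simulation honours the noise model edge cases", {
  ds <- simulate_allopolyploid(zero_cfg(n = 10))
  des_all0 <- expression_design(dropout = 1)
  m0 <- simulate_expression(ds, des_all0, seed = 1)
  expect_true(all(m0 == 0))
  expect_false(any(breadth_and_level(average_timepoints(m0, attr(m0, "design")))$expressed))

  des_const <- expression_design(dropout = 0, log_sd = 0, log_mean = log(10))
  mc <- simulate_expression(ds, des_const, seed = 1)
  expect_equal(unname(mc[1, 1]), 10)
  expect_true(all(abs(mc - 10) < 1e-12))

  m1 <- simulate_expression(ds, seed = 7)
  m2 <- simulate_expression(ds, seed = 7)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(20L, 32L))  # 12 conditions, 32 samples
})

test_that("GO simulation plants enrichment only above odds 1 and propagates to the root", {
  ds <- simulate_allopolyploid(sim_config(n_ancestral_genes = 300, seed = 5))
  go <- simulate_go(ds, enrichment_odds = 1, seed = 8)
  planted_genes <- unique(c(
    ds$truth$gene_a[ds$truth$expected_category == "nonBBH_nonsyntenic"],
    ds$truth$gene_d[ds$truth$expected_category == "nonBBH_nonsyntenic"]))
  in_cat <- go$annotations$gene_id %in% planted_genes &
    go$annotations$term_id == go$planted_term
  freq_in <- sum(in_cat) / length(planted_genes)
  other <- setdiff(ds$genes$gene_id, planted_genes)
  freq_out <- sum(go$annotations$gene_id %in% other &
                  go$annotations$term_id == go$planted_term) / length(other)
  expect_lt(abs(freq_in - freq_out), 0.15)  # null: no planted difference

  ann <- propagate_annotations(go$annotations, go$dag)
  root <- go$dag$terms$id[lengths(go$dag$parents) == 0L]
  annotated <- unique(go$annotations$gene_id)
  expect_setequal(ann$gene_id[ann$term_id == root], annotated)

  expect_error(simulate_go(ds, planted_term = "GO:9999999"), "not in DAG")
  expect_error(simulate_go(ds, planted_category = "bogus"), "planted_category")
  expect_error(simulate_go(ds, enrichment_odds = 0.5), ">= 1")
})
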