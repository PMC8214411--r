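test_that("neighbour windows truncate at scaffold ends and exclude the focal gene", {
  w <- collinear_world(20)
  # position 7 (0-based) of a 20-gene scaffold: 5 on each side
  nb <- neighbor_window("A_g08", w$order, half_window = 5)
  expect_equal(nb, sprintf("A_g%02d", c(3:7, 9:13)))
  # first gene: downstream neighbours only
  expect_equal(neighbor_window("A_g01", w$order, 5), sprintf("A_g%02d", 2:6))
  expect_error(neighbor_window("nope", w$order), "unknown gene")
  # single-gene scaffold: empty window
  solo <- gene_order_index(data.frame(gene_id = "x", subgenome = "A",
                                      scaffold = "s", position = 0))
  expect_equal(length(neighbor_window("x", solo)), 0)
})

test_that("fully collinear interior pairs score 1 and isolated pairs 0", {
  w <- collinear_world(20)
  s <- synteny_score("A_g10", "D_g10", w$index, w$order)
  expect_equal(s$score, 1)
  # a dispersed duplicate alone among unrelated genes
  genes2 <- rbind(w$genes,
                  data.frame(gene_id = c("A_x", sprintf("A_y%d", 1:10)),
                             subgenome = "A", scaffold = "A_s2",
                             position = 0:10, stringsAsFactors = FALSE))
  ord2 <- gene_order_index(genes2)
  idx2 <- homoeologr:::partner_index(rbind(w$pairs,
    data.frame(gene_a = "A_x", gene_d = "D_g10")))
  s0 <- synteny_score("A_x", "D_g10", idx2, ord2)
  expect_equal(s0$score, 0)
})

test_that("a constructed half-matched neighbourhood scores 0.5", {
  # |W_A| = 4 with 2 matched, |W_D| = 4 with 2 matched -> (2+2)/(4+4)
  genes <- data.frame(
    gene_id = c(paste0("a", 1:5), paste0("d", 1:5)),
    subgenome = rep(c("A", "D"), each = 5),
    scaffold = rep(c("sa", "sd"), each = 5),
    position = c(0:4, 0:4), stringsAsFactors = FALSE)
  ord <- gene_order_index(genes)
  pairs <- data.frame(gene_a = c("a3", "a1", "a2"),
                      gene_d = c("d3", "d1", "d2"), stringsAsFactors = FALSE)
  idx <- homoeologr:::partner_index(pairs)
  s <- synteny_score("a3", "d3", idx, ord, half_window = 2, min_neighbors = 2)
  expect_equal(s$score, 0.5)
})

test_that("small scaffolds are excluded with a reason, and counted", {
  genes <- data.frame(gene_id = c("a1", "d1"), subgenome = c("A", "D"),
                      scaffold = c("sa", "sd"), position = c(0, 0))
  ord <- gene_order_index(genes)
  pairs <- data.frame(gene_a = "a1", gene_d = "d1")
  idx <- homoeologr:::partner_index(pairs)
  r <- score_all_pairs(pairs, idx, ord)
  expect_equal(r$n_excluded, 1)
  expect_equal(r$pairs$excluded_reason, "small_scaffold")
  # genes missing from the order entirely are excluded the same way
  r2 <- synteny_score("ghost", "d1", idx, ord)
  expect_equal(r2$reason, "small_scaffold")
})

test_that("score_all_pairs equals elementwise synteny_score on a mixed genome", {
  ds <- simulate_allopolyploid(sim_config(n_ancestral_genes = 80,
                                          outgroup = FALSE, seed = 6))
  pairs <- ds$truth[, c("gene_a", "gene_d")]
  idx <- homoeologr:::partner_index(pairs)
  ord <- gene_order_index(ds$genes)
  r <- score_all_pairs(pairs, idx, ord)
  for (i in sample(nrow(pairs), 15)) {
    expect_equal(r$pairs$synteny_score[i],
                 synteny_score(pairs$gene_a[i], pairs$gene_d[i], idx, ord)$score)
  }
  # conservation: scored + excluded = total
  expect_equal(sum(!is.na(r$pairs$synteny_score)) + r$n_excluded, nrow(pairs))
})

test_that("the score is symmetric and monotone in the relation index", {
  ds <- simulate_allopolyploid(sim_config(n_ancestral_genes = 60,
                                          outgroup = FALSE, seed = 15))
  pairs <- ds$truth[, c("gene_a", "gene_d")]
  ord <- gene_order_index(ds$genes)
  idx <- homoeologr:::partner_index(pairs)
  # symmetry: swap the roles of the two genes (and the index orientation)
  rev_idx <- homoeologr:::partner_index(
    data.frame(gene_a = pairs$gene_d, gene_d = pairs$gene_a))
  for (i in sample(nrow(pairs), 10)) {
    expect_equal(synteny_score(pairs$gene_a[i], pairs$gene_d[i], idx, ord)$score,
                 synteny_score(pairs$gene_d[i], pairs$gene_a[i], rev_idx, ord)$score)
  }
  # monotonicity: adding relations never decreases any score
  sub <- pairs[seq_len(nrow(pairs) - 10), ]
  idx_sub <- homoeologr:::partner_index(sub)
  s_sub <- score_all_pairs(sub, idx_sub, ord)$pairs$synteny_score
  s_full <- score_all_pairs(sub, idx, ord)$pairs$synteny_score
  ok <- !is.na(s_sub)
  expect_true(all(s_full[ok] >= s_sub[ok]))
})

test_that("wider windows keep isolated transposed duplicates nonsyntenic", {
  cfg <- sim_config(n_ancestral_genes = 400, n_scaffolds_per_subgenome = 4,
                    tandem_dup_rate = 0, dispersed_dup_rate = 0,
                    transposition_rate = 0.04, loss_rate = 0,
                    hidden_paralog_rate = 0, outgroup = FALSE, seed = 44)
  ds <- simulate_allopolyploid(cfg)
  pairs <- ds$truth[, c("gene_a", "gene_d")]
  idx <- homoeologr:::partner_index(pairs)
  ord <- gene_order_index(ds$genes)
  tr <- ds$truth$event_class == "transposed"
  # isolated = no cross-window relation even at the widest window tested;
  # nested windows then require a zero score at every narrower size too
  base <- score_all_pairs(pairs, idx, ord, half_window = 20)$pairs$synteny_score
  isolated <- tr & !is.na(base) & base == 0
  expect_gt(sum(isolated), 0)
  for (hw in c(5, 10, 15)) {
    s <- score_all_pairs(pairs, idx, ord, half_window = hw)$pairs$synteny_score
    expect_true(all(s[isolated] == 0, na.rm = TRUE), label = sprintf("hw=%d", hw))
  }
})

test_that("binning follows the 11-category rule with a dedicated zero bin", {
  counts <- bin_scores(c(0, 0, 0.05, 0.1, 1.0))
  expect_equal(unname(counts["0"]), 2)
  expect_equal(unname(counts["(0,0.1]"]), 2)  # 0.05 and 0.1 both in (0, 0.1]
  expect_equal(unname(counts["(0.9,1]"]), 1)
  expect_equal(length(counts), 11)
  expect_equal(sum(counts), 5)
  all0 <- bin_scores(rep(0, 7))
  expect_equal(unname(all0["0"]), 7)
  expect_equal(sum(all0), 7)
  set.seed(1)
  x <- runif(100)
  expect_equal(sum(bin_scores(x)), 100)
  expect_error(bin_scores(c(0.5, 1.2)), "\\[0, 1\\]")
})
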