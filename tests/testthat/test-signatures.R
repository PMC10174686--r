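test_that("hurdle model is calibrated under the null and finds planted DE", {
  # small null: p roughly uniform
  sim <- two_group_counts(n_genes = 150, n_per = 40, seed = 31)
  de <- hurdle_de(sim$matrix, group = cell_metadata(sim$matrix)$group)
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_lt(abs(mean(de$p < 0.2) - 0.2), 0.12)
  # identical gene across groups: LRT ~ 0, p ~ 1
  v <- matrix(rep(c(4, 4), each = 20), 1, 40,
              dimnames = list("gX", sprintf("c%02d", 1:40)))
  v <- rbind(v, gY = rep(c(0, 8), 20))
  em <- expr_matrix(v, tibble::tibble(
    cell_id = colnames(v), mouse = rep(c("m1", "m2"), 20)), units = "TPM")
  de2 <- hurdle_de(em, group = rep(c("M", "NM"), each = 20))
  gx <- de2[de2$gene == "gX", ]
  expect_lt(gx$lrt, 1e-6)
  expect_gt(gx$p, 0.99)
  # planted direction is labelled correctly
  simp <- two_group_counts(n_genes = 200, n_per = 50, de_genes = 20,
                           lfc = 2, seed = 32)
  dep <- hurdle_de(simp$matrix, group = cell_metadata(simp$matrix)$group)
  planted <- sprintf("g%04d", 1:20)
  hit <- dep[dep$gene %in% planted, ]
  expect_gt(mean(hit$fdr < 0.05), 0.9)
  expect_true(all(hit$direction[hit$fdr < 0.05] == "up_in_M"))
  # BH-FDR is monotone in p
  ord <- order(dep$p)
  expect_true(all(diff(dep$fdr[ord]) >= -1e-12))
  # permuting labels destroys planted significance
  perm_g <- withr::with_seed(1, sample(cell_metadata(simp$matrix)$group))
  deperm <- hurdle_de(simp$matrix, group = perm_g)
  expect_gt(median(deperm$fdr[deperm$gene %in% planted]), 0.1)
})

test_that("signature sets split by direction and respect the FDR cut", {
  sim <- two_group_counts(n_genes = 200, n_per = 50, de_genes = 20,
                          lfc = 2, seed = 32)
  de <- hurdle_de(sim$matrix, group = cell_metadata(sim$matrix)$group)
  sets <- signature_gene_sets(de)
  expect_gt(length(intersect(sets$mover, sprintf("g%04d", 1:20))), 17)
  expect_length(intersect(sets$mover, sets$nonmover), 0)
  expect_warning(s0 <- signature_gene_sets(de, fdr_cut = 0), "empty")
  expect_length(s0$mover, 0)
  de1 <- de; de1$fdr <- 1
  expect_warning(s1 <- signature_gene_sets(de1), "empty")
  expect_length(s1$nonmover, 0)
})

test_that("signature scores are background-controlled", {
  sim <- two_group_counts(n_genes = 1000, n_per = 120, seed = 21)
  # background forced equal to signature: exactly zero
  sig <- sprintf("g%04d", 5:24)
  sc0 <- score_cells(sim$matrix, sig, background = sig)
  expect_true(all(sc0$score == 0))
  # adding a constant to every gene of a cell leaves the score unchanged
  sc <- score_cells(sim$matrix, sig)
  m2 <- sim$matrix
  lv <- log2(as.matrix(m2$values) + 1)
  m2$values <- 2^(sweep(lv, 2, rep(1, ncol(lv)), "+")) - 1
  sc_shift <- score_cells(m2, sig, background = attr(sc, "background"))
  expect_equal(sc_shift$score, sc$score, tolerance = 1e-9)
  # background matched on expression and detection, disjoint, 10n genes
  bg <- attr(sc, "background")
  expect_length(intersect(bg, sig), 0)
  expect_length(bg, 10 * length(sig))
  st <- gene_detection_stats(sim$matrix)
  ml <- Matrix::rowMeans(log2(sim$matrix$values + 1))
  expect_lt(abs(mean(ml[bg]) - mean(ml[sig])), 0.35)
  # coverage control: random-set scores unbiased (grand mean across draws)
  grand <- mean(vapply(1:8, function(i) {
    rnd <- withr::with_seed(i, sample(rownames(sim$matrix$values), 25))
    mean(score_cells(sim$matrix, rnd)$score)
  }, numeric(1)))
  expect_lt(abs(grand), 0.05)
  expect_warning(
    score_cells(sim$matrix, rownames(sim$matrix$values)[1:150]),
    "candidate")
})

test_that("mover signature separates planted mover cells (AUC > 0.9)", {
  scn <- plate_scenario(seed = 7)
  sim <- simulate_counts(scn, units = "TPM")
  md <- cell_metadata(sim$matrix)
  emb <- em_subset(sim$matrix, cells = md$cell_id[
    md$group %in% c("mover_basal", "nonmover_basal")])
  sc <- score_cells(emb, attr(scn, "mover_genes"), name = "mover")
  lab <- sc$group == "mover_basal"
  r <- rank(sc$score)
  auc <- (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_gt(auc, 0.9)
})

test_that("score comparisons match exact enumeration and detect planted shifts", {
  s <- tibble::tibble(cell_id = as.character(1:6),
                      score = c(1, 2, 3, 4, 5, 6), signature = "x",
                      group = rep(c("a", "b"), each = 3))
  cmp <- compare_scores(s, "group")
  expect_equal(cmp$U, 0)
  expect_equal(cmp$p, 0.1)
  expect_equal(cmp$p, mw_exact_enum(c(4, 5, 6), c(1, 2, 3)))
  # identical constant groups: p = 1
  s2 <- dplyr::mutate(s, score = 1)
  expect_equal(compare_scores(s2, "group")$p, 1)
  # planted 24 hpi elevation in the injury time course
  inj <- injury_scenario(seed = 3)
  emi <- simulate_counts(inj)$matrix
  sc <- score_cells(emi, sprintf("g%04d", 1:30), name = "mover")
  cmp2 <- compare_scores(sc, group_col = "timepoint",
                         reference = "uninjured")
  expect_lt(cmp2$p[cmp2$group == "24"], 1e-6)
  expect_gt(cmp2$median_diff[cmp2$group == "24"], 0)
})

test_that("SNN clustering recovers planted populations and stays whole when homogeneous", {
  scn <- count_scenario(n_genes = 1500, group_sizes = c(a = 150, b = 150),
                        effects = tibble::tibble(
                          gene = sprintf("g%04d", 1:60),
                          group = rep(c("a", "b"), each = 30), lfc = 4),
                        libsize_meanlog = log(8e3), seed = 5)
  sim <- simulate_counts(scn)
  cl <- snn_cluster(sim$matrix, seed = 5)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(ari(cl$cluster, sim$truth$group), 1)
  # determinism
  cl2 <- snn_cluster(sim$matrix, seed = 5)
  expect_identical(cl, cl2)
  scn0 <- count_scenario(n_genes = 1500, group_sizes = c(a = 200),
                         libsize_meanlog = log(8e3), seed = 6)
  cl0 <- snn_cluster(simulate_counts(scn0)$matrix, seed = 6)
  expect_equal(length(unique(cl0$cluster)), 1)
})
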