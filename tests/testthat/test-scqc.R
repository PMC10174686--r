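qc_fixture <- function() {
  v <- matrix(1, 5, 4, dimnames = list(sprintf("g%d", 1:5),
                                       sprintf("c%d", 1:4)))
  md <- tibble::tibble(cell_id = sprintf("c%d", 1:4),
                       genes_detected = c(999, 5000, 1000, 10001),
                       mapped_fraction = c(0.5, 0.30, 0.25, 0.5))
  expr_matrix(v, md, units = "TPM")
}

test_that("QC filter applies inclusive bounds and logs removals", {
  em <- qc_fixture()
  out <- qc_filter(em)
  kept <- cell_metadata(out)$cell_id
  expect_setequal(kept, c("c2", "c3"))  # 999 out, boundary 1000/0.25 in
  log <- attr(out, "filter_log")
  expect_equal(log$n[log$criterion == "fewer_than_min_genes"], 1)
  expect_equal(log$n[log$criterion == "more_than_max_genes"], 1)
  expect_equal(log$n[log$criterion == "retained"], 2)
  # idempotence
  out2 <- qc_filter(out)
  expect_identical(cell_metadata(out2)$cell_id, kept)
  # all-removed errors with per-criterion breakdown
  expect_error(qc_filter(em, min_genes = 1e6), "fewer_than_min_genes")
})

test_that("variable-gene selection flags under-detected genes only", {
  scn <- count_scenario(n_genes = 800, group_sizes = c(a = 100, b = 100),
                        effects = tibble::tibble(gene = "g0001",
                                                 group = "a", lfc = 6),
                        libsize_meanlog = log(2e4), seed = 8)
  sim <- simulate_counts(scn, units = "TPM")
  vg <- select_variable_genes(sim$matrix)
  expect_true("g0001" %in% vg$genes)         # planted bimodal gene
  st <- vg$stats
  expect_false(any(st$selected[st$detection_fraction == 1]))  # housekeeping
  # on-curve genes have near-zero residuals
  expect_lt(min(abs(st$deviance_residual)), 0.01)
  # gene-order invariance
  perm <- sample(rownames(sim$matrix$values))
  m2 <- sim$matrix
  m2$values <- m2$values[perm, ]
  expect_setequal(select_variable_genes(m2)$genes, vg$genes)
  # depth-scaling invariance
  m3 <- sim$matrix
  m3$values <- m3$values * 7
  expect_setequal(select_variable_genes(m3)$genes, vg$genes)
})

test_that("PCA embedding matches an independent eigendecomposition", {
  set.seed(3)
  v <- matrix(rexp(20 * 20, 0.2), 20, 20,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("c%02d", 1:20)))
  em <- expr_matrix(v, units = "TPM")
  p <- reduce_pca(em, n_pcs = 5)
  x <- scale(t(log2(v + 1)))
  ev <- eigen(cov(x))
  # eigenvalues match prcomp variances
  expect_equal(p$sdev[1:5]^2, ev$values[1:5], tolerance = 1e-8)
  # scores match up to sign
  for (j in 1:3) {
    s_ref <- as.numeric(x %*% ev$vectors[, j])
    s_got <- p$scores[[paste0("PC", j)]]
    expect_equal(abs(cor(s_ref, s_got)), 1, tolerance = 1e-8)
  }
  # loadings orthonormal
  g <- crossprod(p$loadings)
  expect_equal(g, diag(ncol(g)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive
  expect_true(all(apply(p$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  # single dominant axis concentrates variance on PC1
  v2 <- outer(seq_len(10), rep(1, 8)) * 5 +
    matrix(rnorm(80, sd = 1e-3), 10, 8)
  dimnames(v2) <- list(sprintf("g%d", 1:10), sprintf("c%d", 1:8))
  # transpose so the dominant axis varies across cells
  v2t <- t(v2); dimnames(v2t) <- list(sprintf("g%d", 1:8),
                                      sprintf("c%d", 1:10))
  p2 <- reduce_pca(expr_matrix(pmax(v2t, 0), units = "TPM"), n_pcs = 2)
  expect_gt(p2$var_explained[1], 0.99)
  expect_warning(reduce_pca(em, n_pcs = 50), "clipped")
})

test_that("t-SNE layout is seeded and separates well-separated clusters", {
  set.seed(5)
  sc <- rbind(matrix(rnorm(60 * 5), 60, 5),
              matrix(rnorm(60 * 5, mean = 12), 60, 5))
  lab <- rep(c("a", "b"), each = 60)
  y1 <- embed_tsne(sc, seed = 9, perplexity = 15)
  y2 <- embed_tsne(sc, seed = 9, perplexity = 15)
  expect_identical(y1, y2)
  expect_gt(silhouette_mean(cbind(y1$tsne1, y1$tsne2), lab), 0.5)
  # duplicate points land adjacent
  dup <- rbind(sc, sc[1, , drop = FALSE])
  yd <- embed_tsne(dup, seed = 9, perplexity = 15)
  xy <- cbind(yd$tsne1, yd$tsne2)
  d_dup <- sqrt(sum((xy[1, ] - xy[121, ])^2))
  expect_lt(d_dup, quantile(dist(xy), 0.05))
})

test_that("marker clustering recovers identities and flags low-quality cells", {
  scn <- plate_scenario(seed = 3)
  sim <- simulate_counts(scn, units = "TPM")
  markers <- unlist(attr(scn, "markers"), use.names = FALSE)
  cl <- cluster_hierarchical(sim$matrix, markers)
  md <- cell_metadata(sim$matrix)
  truth <- dplyr::case_when(md$group %in% c("mover_basal", "nonmover_basal")
                            ~ "basal",
                            md$group == "club" ~ "club",
                            TRUE ~ "low_quality")
  expect_equal(cl$identity, truth)
  summ <- attr(cl, "cluster_summary")
  lowq <- summ[summ$identity == "low_quality", ]
  expect_lt(lowq$mean_genes_detected,
            min(summ$mean_genes_detected[summ$identity != "low_quality"]))
  expect_lt(lowq$p_low, 0.01)
  # cell-order invariance
  perm <- sample(ncol(sim$matrix$values))
  m2 <- em_subset(sim$matrix, cells = colnames(sim$matrix$values)[perm])
  cl2 <- cluster_hierarchical(m2, markers)
  expect_equal(cl2$identity[match(cl$cell_id, cl2$cell_id)], cl$identity)
  expect_error(cluster_hierarchical(sim$matrix, markers, k = 1e6), "cells")
})
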