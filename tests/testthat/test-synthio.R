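test_that("tissue movie generator is deterministic and conserves structure", {
  scn <- motion_scenario(function(x, y, t) cbind(0 * x, 0 * y),
                         n_nuclei = 50, n_frames = 3, fov_um = c(48, 48),
                         noise_sd = 0.01, seed = 1)
  s1 <- simulate_tissue_movie(scn)
  s2 <- simulate_tissue_movie(scn)
  expect_identical(s1$stack$channels$nuclear, s2$stack$channels$nuclear)
  expect_identical(s1$truth$displacement, s2$truth$displacement)
  expect_equal(dim(s1$stack$channels$nuclear)[4], 3)
  expect_true(all(s1$truth$displacement$u == 0))
  # zero field: consecutive frames identical up to the additive noise
  d <- s1$stack$channels$nuclear[, , 1, 1] - s1$stack$channels$nuclear[, , 1, 2]
  expect_lt(sd(d), 3 * 0.01 / sqrt(2) * 2)
})

test_that("uniform translation moves every nucleus centroid by the planted step", {
  scn <- motion_scenario(function(x, y, t) cbind(rep(3, length(x)), 0 * y),
                         n_nuclei = 12, nucleus_radius = 3, n_frames = 3,
                         fov_um = c(80, 80), noise_sd = 0, seed = 4)
  sim <- simulate_tissue_movie(scn)
  img <- sim$stack$channels$nuclear
  # centroid-fit oracle: intensity-weighted centroid in a window around each
  # planted position
  fit_centroid <- function(frame, x0, y0, r = 6) {
    xs <- max(1, round(x0 + 1 - r)):min(80, round(x0 + 1 + r))
    ys <- max(1, round(y0 + 1 - r)):min(80, round(y0 + 1 + r))
    w <- frame[ys, xs]
    c(sum(outer(rep(1, length(ys)), xs - 1) * w) / sum(w),
      sum(outer(ys - 1, rep(1, length(xs))) * w) / sum(w))
  }
  p1 <- dplyr::filter(sim$truth$positions, frame == 1)
  p2 <- dplyr::filter(sim$truth$positions, frame == 2)
  expect_equal(p2$x - p1$x, rep(3, 12))
  interior <- p1$x > 12 & p1$x < 62 & p1$y > 12 & p1$y < 68
  for (i in which(interior)) {
    c1 <- fit_centroid(img[, , 1, 1], p1$x[i], p1$y[i])
    c2 <- fit_centroid(img[, , 1, 2], p2$x[i], p2$y[i])
    expect_equal(c2[1] - c1[1], 3, tolerance = 0.35)
  }
})

test_that("cilia movie respects sampling theory and planted frequencies", {
  fm <- matrix(8, 6, 6)
  sim <- simulate_cilia_movie(fm, fs = 150, n_frames = 200, seed = 2)
  a <- stack_channel(sim$stack, "surface")
  expect_equal(dim(a)[4], 200)
  # direct DFT periodogram oracle on one pixel trace
  tr <- a[3, 3, 1, ]
  sp <- Mod(fft(tr - mean(tr)))^2
  freqs <- (seq_along(sp) - 1) * 150 / length(sp)
  half <- freqs <= 75
  peak <- freqs[half][which.max(sp[half][-1]) + 1]
  expect_lt(abs(peak - 8), 150 / 200)
  expect_error(simulate_cilia_movie(matrix(80, 4, 4), fs = 150),
               "Nyquist")
  # amplitude 0: constant plus noise
  s0 <- simulate_cilia_movie(fm, fs = 150, n_frames = 50, amplitude = 0,
                             noise_sd = 0.05, seed = 3)
  tr0 <- stack_channel(s0$stack, "surface")[1, 1, 1, ]
  expect_lt(sd(tr0), 0.1)
  # two-region truth map is carried through
  fm2 <- cbind(matrix(6, 4, 2), matrix(10, 4, 2))
  s2 <- simulate_cilia_movie(fm2, seed = 1)
  expect_identical(s2$truth$freq_map, fm2)
})

test_that("count generator plants effects, mice and depth-linked dropout", {
  # planted log2FC = 2 recovered as ~4x group-mean ratio at large n
  sim <- two_group_counts(n_genes = 200, n_per = 500, de_genes = 1,
                          lfc = 2, seed = 9, units = "counts")
  v <- as.matrix(sim$matrix$values)
  g <- sim$matrix$metadata$group
  ratio <- mean(v["g0001", g == "M"]) / mean(v["g0001", g == "NM"])
  expect_equal(ratio, 4, tolerance = 0.3)
  # conservation and determinism
  expect_equal(ncol(v), 1000)
  sim2 <- two_group_counts(n_genes = 200, n_per = 500, de_genes = 1,
                           lfc = 2, seed = 9, units = "counts")
  expect_identical(v, as.matrix(sim2$matrix$values))
  # null scenario: per-gene means exchangeable across groups
  null <- two_group_counts(n_genes = 300, n_per = 100, seed = 5,
                           units = "counts")
  vn <- as.matrix(null$matrix$values)
  gn <- null$matrix$metadata$group
  lfcs <- log2((rowMeans(vn[, gn == "M"]) + 1) /
                 (rowMeans(vn[, gn == "NM"]) + 1))
  expect_lt(abs(mean(lfcs)), 0.1)
  # depth-linked detection: genes detected grows with library size
  expect_gt(cor(null$matrix$metadata$genes_detected,
                log(null$truth$libsize)), 0.5)
  expect_error(count_scenario(n_genes = 10, group_sizes = c(a = 0)),
               "positive")
})

test_that("low-quality group separates on detected genes as in plate data", {
  scn <- plate_scenario(seed = 3)
  sim <- simulate_counts(scn, units = "TPM")
  md <- sim$matrix$metadata
  lowq <- md$genes_detected[md$group == "low_quality"]
  good <- md$genes_detected[md$group != "low_quality"]
  expect_lt(max(lowq), min(good))
  expect_lt(wilcox.test(lowq, good, alternative = "less")$p.value, 1e-10)
})
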