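# shared fixtures and small independent oracles used across test files

# dense particle-like texture pair with a planted uniform shift (um == px)
textured_pair <- function(shift_x, shift_y = 0, n = 2000, sigma = 0.8,
                          size = 64, seed = 1) {
  withr::with_seed(seed, {
    pos <- cbind(runif(n, -8, size + 8), runif(n, -8, size + 8))
    a <- behavex:::render_blobs(pos, sigma, size, size, 1)
    b <- behavex:::render_blobs(pos + cbind(rep(shift_x, n),
                                            rep(shift_y, n)),
                                sigma, size, size, 1)
    list(a = a, b = b)
  })
}

# full-search integer-shift cross-correlation oracle: for every grid point,
# the integer displacement maximising the dot product of de-meaned windows
full_search_oracle <- function(frame_a, frame_b, grid_x, grid_y,
                               window = 16, max_shift = 8) {
  half <- window / 2
  best <- matrix(NA_real_, length(grid_x), 3)
  for (k in seq_along(grid_x)) {
    cx <- grid_x[k] + 1; cy <- grid_y[k] + 1
    rows <- (cy - half + 1):(cy + half)
    cols <- (cx - half + 1):(cx + half)
    A <- frame_a[rows, cols]; A <- A - mean(A)
    best_val <- -Inf
    for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
      rb <- rows + dy; cb <- cols + dx
      if (min(rb) < 1 || max(rb) > nrow(frame_b) ||
          min(cb) < 1 || max(cb) > ncol(frame_b)) next
      B <- frame_b[rb, cb]; B <- B - mean(B)
      v <- sum(A * B)
      if (v > best_val) { best_val <- v; best[k, ] <- c(dx, dy, v) }
    }
  }
  best
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b); n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2)); sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# mean silhouette width of a labelling on 2D coordinates
silhouette_mean <- function(xy, labels) {
  d <- as.matrix(dist(xy))
  s <- vapply(seq_len(nrow(xy)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(xy)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# exact two-sided Mann-Whitney p for tiny samples by full enumeration
mw_exact_enum <- function(x, y) {
  pooled <- c(x, y); n1 <- length(x)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, "<")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_of)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(all_u - mu) >= abs(obs - mu))
}

# quick two-group count fixture
two_group_counts <- function(n_genes = 300, n_per = 50, de_genes = 0,
                             lfc = 2, seed = 1, units = "TPM",
                             libsize_meanlog = log(2e4)) {
  eff <- if (de_genes > 0)
    tibble::tibble(gene = sprintf("g%04d", seq_len(de_genes)),
                   group = "M", lfc = lfc)
  else tibble::tibble(gene = character(), group = character(),
                      lfc = numeric())
  scn <- count_scenario(n_genes = n_genes,
                        group_sizes = c(M = n_per, NM = n_per),
                        effects = eff, libsize_meanlog = libsize_meanlog,
                        seed = seed)
  simulate_counts(scn, units = units)
}
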