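# ridge-stabilised logistic fit used when a component separates completely;
# returns the deviance of a weakly penalised IRLS solution
ridge_logistic_deviance <- function(X, y, lambda = 1e-2, iter = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    beta_new <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  p <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}

fit_detection_lrt <- function(det, group, covars) {
  X_full <- stats::model.matrix(~., data = cbind(group = group, covars))
  X_red <- stats::model.matrix(~., data = covars)
  f_full <- suppressWarnings(glm.fit(X_full, det, family = binomial()))
  f_red <- suppressWarnings(glm.fit(X_red, det, family = binomial()))
  coefs <- f_full$coefficients
  sep <- isTRUE(!f_full$converged || any(abs(coefs) > 15, na.rm = TRUE) ||
                  is.na(coefs["group"]))
  if (sep) {
    dev_full <- ridge_logistic_deviance(X_full, det)
    dev_red <- ridge_logistic_deviance(X_red, det)
    co <- NA_real_
    lrt <- max(0, dev_red - dev_full)
  } else {
    co <- unname(coefs["group"])
    lrt <- max(0, f_red$deviance - f_full$deviance)
  }
  list(lrt = lrt, coef = co, flagged = sep)
}

fit_continuous_lrt <- function(y, group, covars) {
  covars <- droplevels(covars)
  fac <- vapply(covars, is.factor, TRUE)
  if (any(fac)) {
    ok <- !fac | vapply(covars, function(c) nlevels(c) >= 2, TRUE)
    covars <- covars[, ok, drop = FALSE]
  }
  df_full <- cbind(y = y, group = group, covars)
  f_full <- lm(y ~ ., data = df_full)
  f_red <- lm(y ~ ., data = cbind(y = y, covars))
  if (anyNA(coef(f_full)["group"])) return(NULL)
  n <- length(y)
  rss_full <- sum(stats::residuals(f_full)^2)
  rss_red <- sum(stats::residuals(f_red)^2)
  if (rss_full < 1e-12) return(NULL)
  # Bartlett-type small-sample scaling of the Gaussian LRT: use the
  # residual degrees of freedom instead of n so the chi-square reference
  # holds at the few dozen expressing cells typical per gene
  list(lrt = max(0, f_full$df.residual * log(rss_red / rss_full)),
       coef = unname(coef(f_full)["group"]))
}

#' Two-part hurdle differential expression
#'
#' For every gene, a detection component (logistic regression of presence
#' on group, cellular detection rate and mouse) and a continuous component
#' (Gaussian regression of log2(value + 1) on the same covariates over
#' expressing cells) are fitted; the likelihood-ratio statistics for
#' dropping the group term are summed and referred to a chi-square whose
#' degrees of freedom count the estimable components (2, or 1 when a
#' component is inestimable, recorded per gene). p values are Benjamini-
#' Hochberg adjusted. The cellular detection rate covariate absorbs
#' technical quality and the mouse factor absorbs animal-to-animal
#' variation.
#'
#' @param m An [expr_matrix()] (TPM or counts) restricted to the cells
#'   under test (e.g. basal cells only, low-quality excluded).
#' @param group Per-cell two-level factor or character (e.g. "M"/"NM"); the
#'   reported coefficients refer to the second level relative to the first
#'   (alphabetical when character).
#' @param mouse Optional per-cell mouse factor (taken from metadata column
#'   `mouse` when present).
#' @param min_cells_continuous Minimum expressing cells required to fit the
#'   continuous component.
#' @return Tibble of class `hurdle_de`: per gene, `coef_detection`,
#'   `coef_continuous`, `lrt`, `df`, `p`, `fdr`, `direction`
#'   (`up_in_<level2>` / `up_in_<level1>`), `flagged`.
#' @export
hurdle_de <- function(m, group = NULL, mouse = NULL,
                      min_cells_continuous = 3) {
  md <- m$metadata
  group <- group %||% md$condition
  check_that(!is.null(group) && length(group) == ncol(m$values),
             "need one group label per cell")
  group <- factor(group)
  check_that(nlevels(group) == 2, "group must have exactly two levels")
  check_that(all(table(group) >= 3), "each group needs at least 3 cells")
  mouse <- mouse %||% md$mouse
  v <- as.matrix(m$values)
  cdr <- colMeans(v > 0)
  covars <- data.frame(cdr = as.numeric(scale(cdr)))
  if (!is.null(mouse) && length(unique(mouse)) > 1)
    covars$mouse <- factor(mouse)
  g01 <- as.numeric(group) - 1
  lev <- levels(group)
  res <- purrr::map_dfr(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    det <- as.numeric(x > 0)
    nd <- sum(det)
    lrt <- 0; df <- 0L
    coef_d <- NA_real_; coef_c <- NA_real_; flagged <- FALSE
    if (nd > 0 && nd < length(det)) {
      fd <- fit_detection_lrt(det, g01, covars)
      lrt <- lrt + fd$lrt; df <- df + 1L
      coef_d <- fd$coef; flagged <- fd$flagged
    }
    pos <- which(det == 1)
    if (length(pos) >= min_cells_continuous &&
        length(unique(g01[pos])) == 2) {
      y <- log2(x[pos] + 1)
      if (sd(y) > 0) {
        fc <- fit_continuous_lrt(y, g01[pos],
                                 covars[pos, , drop = FALSE])
        if (!is.null(fc)) {
          lrt <- lrt + fc$lrt; df <- df + 1L
          coef_c <- fc$coef
        }
      }
    }
    p <- if (df > 0) pchisq(lrt, df = df, lower.tail = FALSE) else 1
    eff <- sum(c(coef_c, coef_d), na.rm = TRUE)
    dir <- if (is.na(coef_c) && is.na(coef_d)) NA_character_
      else if (eff >= 0) paste0("up_in_", lev[2]) else paste0("up_in_", lev[1])
    tibble(gene = rownames(v)[i], coef_detection = coef_d,
           coef_continuous = coef_c, lrt = lrt, df = df, p = p,
           direction = dir, flagged = flagged)
  })
  res$fdr <- p.adjust(res$p, method = "BH")
  res <- dplyr::relocate(res, "fdr", .after = "p")
  attr(res, "levels") <- lev
  class(res) <- c("hurdle_de", class(res))
  res
}

#' Directional signature gene sets from a DE result
#'
#' @param de A [hurdle_de()] result.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return List with `mover` (genes up in the second group level, typically
#'   "NM" vs "M" ordering is handled via the recorded levels: the set up in
#'   the mover condition) and `nonmover`; disjoint by construction.
#' @export
signature_gene_sets <- function(de, fdr_cut = 0.05) {
  lev <- attr(de, "levels") %||% c("M", "NM")
  mover_lab <- paste0("up_in_", if ("M" %in% lev) "M" else lev[1])
  nonmover_lab <- setdiff(paste0("up_in_", lev), mover_lab)
  sig <- dplyr::filter(de, .data$fdr < fdr_cut, !is.na(.data$direction))
  out <- list(mover = sig$gene[sig$direction == mover_lab],
              nonmover = sig$gene[sig$direction == nonmover_lab])
  if (!length(out$mover) && !length(out$nonmover))
    warn("no genes pass the FDR cut; both signature sets are empty")
  out
}

#' Expression-matched background gene set
#'
#' For each signature gene, its nearest non-signature neighbours in the 2D
#' space of mean log expression and detection frequency (each axis
#' z-scaled) are collected; the deduplicated union is topped up with the
#' next-nearest candidates until it holds `multiple` genes per signature
#' gene. Ties break deterministically by gene id.
#'
#' @param m An [expr_matrix()].
#' @param signature Character vector of signature genes.
#' @param multiple Background genes per signature gene (default 10).
#' @return Character vector of background genes (disjoint from the
#'   signature).
#' @export
matched_background <- function(m, signature, multiple = 10) {
  signature <- intersect(signature, rownames(m$values))
  check_that(length(signature) >= 1, "no signature genes in the matrix")
  st <- gene_detection_stats(m)
  # mean log expression: the same per-gene quantity the score averages, so
  # matched background genes cancel coverage effects on the score scale
  st$mean_log <- Matrix::rowMeans(log2(m$values + 1))[st$gene]
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  space <- cbind(zs(st$mean_log), zs(st$detection_fraction))
  rownames(space) <- st$gene
  cand <- setdiff(st$gene, signature)
  target <- multiple * length(signature)
  if (length(cand) < target) {
    warn(sprintf("only %d candidate genes for a background of %d; using all",
                 length(cand), target))
    return(sort(cand))
  }
  sig_xy <- space[signature, , drop = FALSE]
  cand_xy <- space[cand, , drop = FALSE]
  d2 <- outer(cand_xy[, 1], sig_xy[, 1], "-")^2 +
    outer(cand_xy[, 2], sig_xy[, 2], "-")^2
  # per signature gene, candidates ranked by distance (ties by gene id);
  # take each gene's `multiple` nearest, dedupe, then top up round-robin
  # with the next-nearest so the set stays locally matched
  ranked <- lapply(seq_along(signature), function(j)
    cand[order(d2[, j], cand)])
  chosen <- character(0)
  for (r in seq_along(cand)) {
    for (j in seq_along(ranked)) {
      g <- ranked[[j]][r]
      if (!(g %in% chosen)) chosen <- c(chosen, g)
      if (length(chosen) >= target) break
    }
    if (length(chosen) >= target) break
  }
  sort(chosen)
}

#' Background-controlled signature scores per cell
#'
#' Score = mean log2(value + 1) over the signature genes minus the mean
#' over an expression-matched background ([matched_background()]) 10x the
#' signature's size, controlling for sequencing coverage and library
#' complexity.
#'
#' @param m An [expr_matrix()].
#' @param signature Character vector of signature genes.
#' @param name Signature name carried into the result.
#' @param multiple Background size multiple (default 10).
#' @param background Optional explicit background set (overrides matching;
#'   used for controls).
#' @return Tibble of class `signature_score`: per cell `cell_id`, `score`,
#'   `signature`, joined with the matrix metadata; background genes in
#'   attribute `"background"`.
#' @export
score_cells <- function(m, signature, name = "signature", multiple = 10,
                        background = NULL) {
  signature <- intersect(signature, rownames(m$values))
  check_that(length(signature) >= 1, "no signature genes in the matrix")
  background <- background %||% matched_background(m, signature, multiple)
  lv <- log2(as.matrix(m$values) + 1)
  sig_mean <- colMeans(lv[signature, , drop = FALSE])
  bg_mean <- colMeans(lv[background, , drop = FALSE])
  out <- tibble(cell_id = colnames(m$values), score = sig_mean - bg_mean,
                signature = name)
  out <- dplyr::left_join(out, m$metadata, by = "cell_id")
  attr(out, "background") <- background
  attr(out, "signature_genes") <- signature
  class(out) <- c("signature_score", class(out))
  out
}

#' Compare signature scores between groups (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U tests of the score between a reference group
#' and every other group (exact for small samples without ties, tie-
#' corrected normal approximation otherwise).
#'
#' @param scores A [score_cells()] tibble.
#' @param group_col Metadata column defining groups.
#' @param reference Reference level; default: each group vs all others
#'   pairwise against the first sorted level.
#' @return Tibble: `group`, `reference`, `n`, `n_ref`, `U`, `p`,
#'   `median_diff`.
#' @export
compare_scores <- function(scores, group_col = "group", reference = NULL) {
  check_that(group_col %in% names(scores), "grouping column not found")
  g <- as.character(scores[[group_col]])
  lev <- sort(unique(g))
  check_that(length(lev) >= 2, "need at least two groups")
  reference <- reference %||% lev[1]
  check_that(reference %in% lev, "reference level not present")
  others <- setdiff(lev, reference)
  ref_scores <- scores$score[g == reference]
  purrr::map_dfr(others, function(l) {
    x <- scores$score[g == l]
    wt <- suppressWarnings(wilcox.test(x, ref_scores))
    W <- unname(wt$statistic)
    tibble(group = l, reference = reference,
           n = length(x), n_ref = length(ref_scores),
           U = min(W, length(x) * length(ref_scores) - W),
           p = if (all(x == x[1]) && all(ref_scores == x[1])) 1
               else wt$p.value,
           median_diff = median(x) - median(ref_scores))
  })
}

# vst-style highly variable genes: standardized variance of clipped
# z-scores under a loess fit of log10(variance) on log10(mean)
vst_hvg <- function(counts, n_top = 2000, loess_span = 0.3) {
  mu <- Matrix::rowMeans(counts)
  v <- apply(counts, 1, var)
  keep <- mu > 0 & v > 0
  fit <- loess(log10(v[keep]) ~ log10(mu[keep]), span = loess_span)
  sd_exp <- sqrt(10^predict(fit))
  n <- ncol(counts)
  clip <- sqrt(n)
  z <- sweep(counts[keep, , drop = FALSE], 1, mu[keep], "-")
  z <- sweep(z, 1, sd_exp, "/")
  z <- pmin(pmax(z, -clip), clip)
  std_var <- Matrix::rowSums(z^2) / (n - 1)
  ord <- order(std_var, decreasing = TRUE)
  rownames(counts)[keep][head(ord, n_top)]
}

#' Shared-nearest-neighbor graph clustering
#'
#' The droplet-arm clustering route: vst-style highly variable genes (top
#' 2000 by standardized variance after a smooth mean-variance fit),
#' depth-normalised log counts, PCA to `n_pcs`, a k-nearest-neighbour graph
#' whose edges are weighted by the Jaccard overlap of neighbour sets
#' (pruned below 1/15), and Louvain modularity optimisation at the given
#' resolution. Seeded; singletons disconnected from the graph keep their
#' own cluster.
#'
#' @param m An [expr_matrix()] of counts.
#' @param n_pcs Principal components (default 25).
#' @param resolution Modularity resolution (default 0.25).
#' @param k_neighbors Neighbours per cell (default 20).
#' @param n_hvg Number of variable genes.
#' @param prune Jaccard pruning threshold.
#' @param seed RNG seed for the community search.
#' @return Tibble of class `cluster_labels`: `cell_id`, `cluster`
#'   (0-based, ordered by decreasing size).
#' @export
snn_cluster <- function(m, n_pcs = 25, resolution = 0.25, k_neighbors = 20,
                        n_hvg = 2000, prune = 1 / 15, seed = 1L) {
  n <- ncol(m$values)
  check_that(n >= k_neighbors + 1, "need at least k_neighbors + 1 cells")
  counts <- as.matrix(m$values)
  hvg <- vst_hvg(counts, n_top = n_hvg)
  depth <- colSums(counts)
  norm <- log1p(sweep(counts[hvg, , drop = FALSE], 2, depth, "/") * 1e4)
  x <- t(norm)
  keep <- apply(x, 2, sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  n_pcs <- min(n_pcs, min(dim(x)) - 1L)
  pcs <- prcomp(x, center = FALSE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                     drop = FALSE]
  dm <- as.matrix(dist(pcs))
  # neighbour sets include the cell itself; SNN weight = Jaccard overlap of
  # the k-nearest-neighbour sets for every pair of cells, pruned
  M <- matrix(0, n, n)
  for (i in seq_len(n)) M[i, order(dm[i, ])[seq_len(k_neighbors)]] <- 1
  ov <- tcrossprod(M)
  adj <- ov / (2 * k_neighbors - ov)
  adj[adj < prune] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  comm <- with_local_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  # merge connected singleton communities into the neighbouring cluster
  # with the strongest total SNN weight; a truly disconnected cell keeps
  # its own cluster
  repeat {
    sizes0 <- table(memb)
    singles <- as.integer(names(sizes0)[sizes0 == 1])
    moved <- FALSE
    for (s in singles) {
      i <- which(memb == s)
      wts <- adj[i, ]
      if (all(wts == 0)) next
      tgt <- tapply(wts, memb, sum)
      tgt <- tgt[names(tgt) != as.character(s)]
      if (!length(tgt) || max(tgt) == 0) next
      memb[i] <- as.integer(names(tgt)[which.max(tgt)])
      moved <- TRUE
    }
    if (!moved) break
  }
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- tibble(cell_id = colnames(m$values),
                cluster = unname(relabel[as.character(memb)]))
  class(out) <- c("cluster_labels", class(out))
  out
}
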