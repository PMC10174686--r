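#' Quality-control filter for cells
#'
#' Keeps cells with `min_genes <= genes_detected <= max_genes` and
#' `mapped_fraction >= min_mapped`. Both boundaries are inclusive: the
#' exclusion rules are "fewer than", "more than" and "less than". A filter
#' log recording the number of cells removed per criterion is attached as
#' attribute `"filter_log"`.
#'
#' @param m An [expr_matrix()].
#' @param min_genes,max_genes Detected-gene bounds (defaults 1000 / 10000).
#' @param min_mapped Minimum fraction of reads mapped (default 0.25).
#' @return A filtered [expr_matrix()].
#' @export
qc_filter <- function(m, min_genes = 1000, max_genes = 10000,
                      min_mapped = 0.25) {
  md <- m$metadata
  check_that(all(c("genes_detected", "mapped_fraction") %in% names(md)),
             "metadata must carry genes_detected and mapped_fraction")
  too_few <- md$genes_detected < min_genes
  too_many <- md$genes_detected > max_genes
  low_map <- md$mapped_fraction < min_mapped
  keep <- !(too_few | too_many | low_map)
  log <- tibble(criterion = c("fewer_than_min_genes", "more_than_max_genes",
                              "low_mapped_fraction", "retained"),
                n = c(sum(too_few), sum(too_many), sum(low_map), sum(keep)))
  if (!any(keep)) {
    abort(paste0("no cells survive QC (",
                 paste(sprintf("%s: %d", log$criterion[1:3], log$n[1:3]),
                       collapse = ", "), ")"))
  }
  out <- em_subset(m, cells = md$cell_id[keep])
  attr(out, "filter_log") <- log
  out
}

#' Per-gene detection statistics
#'
#' @param m An [expr_matrix()].
#' @return Tibble with `gene`, `mean_expression`, `detection_fraction`
#'   (cells with value > 0 over all cells) and `total_transcripts`.
#' @export
gene_detection_stats <- function(m) {
  v <- m$values
  tibble(gene = rownames(v),
         mean_expression = Matrix::rowMeans(v),
         detection_fraction = Matrix::rowMeans(v > 0),
         total_transcripts = Matrix::rowSums(v))
}

#' Select variable genes by detection-fraction deviance
#'
#' A single logistic curve is fitted across genes relating each gene's
#' cellular detection fraction to the log10 of its total transcript count;
#' genes detected in a lower fraction of cells than the curve predicts for
#' their abundance (signed binomial deviance residual below `threshold`)
#' are cell-type- or state-specific and selected as variable.
#'
#' @param m An [expr_matrix()].
#' @param threshold Deviance-residual cut-off (default -0.15; residuals
#'   below it are selected).
#' @return List with `genes` (character vector of selected genes) and
#'   `stats` (the detection tibble plus `deviance_residual`, `expected`,
#'   `selected`).
#' @export
select_variable_genes <- function(m, threshold = -0.15) {
  check_that(nrow(m$values) >= 2 && ncol(m$values) >= 2,
             "need at least two genes and two cells")
  st <- gene_detection_stats(m)
  st <- dplyr::filter(st, .data$total_transcripts > 0)
  check_that(nrow(st) >= 2, "need at least two expressed genes")
  if (all(st$detection_fraction == 0) || all(st$detection_fraction == 1))
    abort("degenerate detection: all fractions identical at 0 or 1")
  n_cells <- ncol(m$values)
  det <- round(st$detection_fraction * n_cells)
  fit <- glm(cbind(det, n_cells - det) ~ log10(st$total_transcripts),
             family = binomial())
  st$expected <- as.numeric(fit$fitted.values)
  # signed deviance residual of the aggregated binomial observation,
  # scaled to per-cell magnitude so the cut-off does not grow with n
  st$deviance_residual <-
    as.numeric(stats::residuals(fit, type = "deviance")) / sqrt(n_cells)
  st$selected <- st$deviance_residual < threshold
  st <- dplyr::arrange(st, .data$deviance_residual)
  list(genes = st$gene[st$selected], stats = st)
}

#' PCA embedding of log-transformed expression
#'
#' Restricts to the given genes, log2(x + 1)-transforms, centres and unit-
#' scales each gene across cells, and runs PCA keeping the first `n_pcs`
#' scores. Component signs follow the convention that each PC's largest-
#' magnitude gene loading is positive.
#'
#' @param m An [expr_matrix()].
#' @param genes Genes to use (e.g. from [select_variable_genes()]).
#' @param n_pcs Number of components to keep (default 20; clipped with a
#'   warning if it exceeds the data rank).
#' @return Object of class `behavex_pca`: list with `scores` (tibble,
#'   `cell_id` + `PC1..PCn`), `loadings`, `sdev`, `var_explained`.
#' @export
reduce_pca <- function(m, genes = NULL, n_pcs = 20) {
  genes <- genes %||% rownames(m$values)
  check_that(all(genes %in% rownames(m$values)),
             "genes not all present in the matrix")
  x <- t(log2(as.matrix(m$values[genes, , drop = FALSE]) + 1))
  keep <- apply(x, 2, sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  max_pc <- min(dim(x)) - 1L
  if (n_pcs > max_pc) {
    warn(sprintf("n_pcs clipped from %d to %d", n_pcs, max_pc))
    n_pcs <- max_pc
  }
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  rot <- p$rotation[, seq_len(n_pcs), drop = FALSE]
  sco <- p$x[, seq_len(n_pcs), drop = FALSE]
  flip <- vapply(seq_len(n_pcs), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  sco <- sweep(sco, 2, flip, "*")
  scores <- as_tibble(sco)
  scores <- dplyr::mutate(scores, cell_id = colnames(m$values), .before = 1)
  structure(list(scores = scores, loadings = rot, sdev = p$sdev,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 n_pcs = n_pcs),
            class = "behavex_pca")
}

#' @export
print.behavex_pca <- function(x, ...) {
  cat(sprintf("<behavex_pca> %d cells, %d PCs (%.1f%% variance)\n",
              nrow(x$scores), x$n_pcs,
              100 * sum(x$var_explained[seq_len(x$n_pcs)])))
  invisible(x)
}

#' Barnes-Hut t-SNE layout of a PCA embedding
#'
#' Visualization only: nothing downstream consumes the layout. Seeded for
#' reproducibility.
#'
#' @param pca A `behavex_pca` (or a numeric matrix of scores).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity (clipped for small n).
#' @return Tibble with `cell_id`, `tsne1`, `tsne2`.
#' @export
embed_tsne <- function(pca, seed = 1L, perplexity = 30) {
  if (inherits(pca, "behavex_pca")) {
    ids <- pca$scores$cell_id
    x <- as.matrix(dplyr::select(pca$scores, -"cell_id"))
  } else {
    x <- as.matrix(pca)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  check_that(nrow(x) >= 5, "need at least 5 cells")
  perplexity <- min(perplexity, floor((nrow(x) - 1) / 3))
  res <- with_local_seed(seed,
    Rtsne::Rtsne(x, perplexity = perplexity, pca = FALSE,
                 check_duplicates = FALSE))
  tibble(cell_id = ids, tsne1 = res$Y[, 1], tsne2 = res$Y[, 2])
}

#' Marker-guided hierarchical clustering with identity assignment
#'
#' Cells are clustered on the marker-gene-restricted log2 matrix with
#' distance = 1 - Pearson correlation and Ward-type ("ward.D2") linkage,
#' cut at `k`. The cluster with dominant basal-marker expression is labelled
#' `basal`, the one with dominant secretory markers `club`, and any cluster
#' whose detected-gene counts are significantly depressed versus all other
#' cells (one-sided Mann-Whitney, p below `lowq_p`) is labelled
#' `low_quality` and should be excluded from differential expression.
#'
#' @param m An [expr_matrix()].
#' @param marker_genes Character vector of marker genes present in the
#'   matrix.
#' @param k Number of clusters (default 3).
#' @param basal_markers,club_markers Identity marker subsets (defaults
#'   [behavex_basal_markers] and [behavex_club_markers], intersected with
#'   `marker_genes`).
#' @param lowq_p Mann-Whitney p cut-off for the low-quality call.
#' @return Tibble of class `cluster_labels`: `cell_id`, `cluster` (integer),
#'   `identity` (basal / club / low_quality / unassigned).
#' @export
cluster_hierarchical <- function(m, marker_genes,
                                 k = 3,
                                 basal_markers = behavex_basal_markers,
                                 club_markers = behavex_club_markers,
                                 lowq_p = 0.01) {
  check_that(all(marker_genes %in% rownames(m$values)),
             "marker genes missing from matrix")
  n <- ncol(m$values)
  check_that(k <= n, "k exceeds the number of cells")
  x <- log2(as.matrix(m$values[marker_genes, , drop = FALSE]) + 1)
  cc <- suppressWarnings(cor(x))
  cc[!is.finite(cc)] <- 0  # constant profiles: no correlation information
  d <- as.dist(1 - cc)
  hc <- hclust(d, method = "ward.D2")
  cl <- cutree(hc, k = k)
  md <- m$metadata
  basal_markers <- intersect(basal_markers, marker_genes)
  club_markers <- intersect(club_markers, marker_genes)
  mean_marker <- function(genes, cells) {
    if (!length(genes)) return(NA_real_)
    mean(x[genes, cells, drop = FALSE])
  }
  ids <- sort(unique(cl))
  summ <- purrr::map_dfr(ids, function(ci) {
    cells <- which(cl == ci)
    other <- which(cl != ci)
    p_low <- if (length(other))
      wilcox.test(md$genes_detected[cells], md$genes_detected[other],
                  alternative = "less", exact = FALSE)$p.value else 1
    tibble(cluster = ci,
           basal_score = mean_marker(basal_markers, cells),
           club_score = mean_marker(club_markers, cells),
           mean_genes_detected = mean(md$genes_detected[cells]),
           p_low = p_low)
  })
  identity <- rep("unassigned", length(ids))
  lowq <- which(summ$p_low < lowq_p)
  identity[lowq] <- "low_quality"
  rest <- setdiff(seq_along(ids), lowq)
  if (length(rest)) {
    bi <- rest[which.max(summ$basal_score[rest] - summ$club_score[rest])]
    identity[bi] <- "basal"
    rest2 <- setdiff(rest, bi)
    if (length(rest2)) {
      ci2 <- rest2[which.max(summ$club_score[rest2])]
      if (is.finite(summ$club_score[ci2])) identity[ci2] <- "club"
    }
  }
  out <- tibble(cell_id = md$cell_id, cluster = unname(cl),
                identity = identity[match(cl, ids)])
  attr(out, "cluster_summary") <- dplyr::mutate(summ,
    identity = identity[match(.data$cluster, ids)])
  class(out) <- c("cluster_labels", class(out))
  out
}
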