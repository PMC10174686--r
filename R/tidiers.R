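#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hurdle DE result
#'
#' One row per gene with the model statistics, ordered by p value.
#'
#' @param x A [hurdle_de()] result.
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy hurdle_de
tidy.hurdle_de <- function(x, ...) {
  out <- as_tibble(x)
  dplyr::arrange(out, .data$p)
}

#' One-line summary of a hurdle DE result
#'
#' @param x A [hurdle_de()] result.
#' @param fdr_cut Significance threshold on the FDR.
#' @param ... Ignored.
#' @return A one-row tibble: genes tested, significant, flagged, and the
#'   contrast levels.
#' @exportS3Method generics::glance hurdle_de
glance.hurdle_de <- function(x, fdr_cut = 0.05, ...) {
  lev <- attr(x, "levels") %||% c(NA, NA)
  tibble(n_genes = nrow(x),
         n_significant = sum(x$fdr < fdr_cut, na.rm = TRUE),
         n_flagged = sum(x$flagged),
         level_1 = lev[1], level_2 = lev[2])
}

#' Tidy a PCA embedding: long table of scores
#'
#' @param x A `behavex_pca` from [reduce_pca()].
#' @param ... Ignored.
#' @return Tibble with `cell_id`, `pc`, `score`.
#' @exportS3Method generics::tidy behavex_pca
tidy.behavex_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"cell_id", names_to = "pc",
                      values_to = "score")
}

#' One-line summary of a PCA embedding
#'
#' @param x A `behavex_pca`.
#' @param ... Ignored.
#' @return One-row tibble: cells, PCs kept, variance captured.
#' @exportS3Method generics::glance behavex_pca
glance.behavex_pca <- function(x, ...) {
  tibble(n_cells = nrow(x$scores), n_pcs = x$n_pcs,
         var_captured = sum(x$var_explained[seq_len(x$n_pcs)]))
}
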