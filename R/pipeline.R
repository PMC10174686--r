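#' Default end-to-end run configuration
#'
#' Nested list of every stage's parameters with the package defaults: a
#' two-speed synthetic movie (slow and fast halves at 0.5 and 5 um/hr), the
#' plate-based mover/non-mover count scenario, QC bounds, variable-gene and
#' PCA settings, hurdle-DE FDR cut, signature-scoring background multiple,
#' and the injury time-course used for cross-dataset scoring.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `run_config` list, serialisable to YAML.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    movie = list(fov_um = c(96, 96), n_frames = 6, frame_interval = 3600,
                 n_nuclei = 220, nucleus_radius = 4, noise_sd = 0.02,
                 slow_um_hr = 0.5, fast_um_hr = 5),
    piv = list(passes_um = c(24, 16, 10), grid_spacing = 10,
               min_peak_ratio = 1.3),
    classify = list(low = 1.5, high = 4),
    counts = list(n_genes = 2000, n_signature = 30, signature_lfc = 2),
    qc = list(min_genes = 200, max_genes = 10000, min_mapped = 0.25),
    hvg = list(deviance_threshold = -0.15),
    pca = list(n_pcs = 20),
    de = list(fdr_cut = 0.05),
    score = list(background_multiple = 10),
    snn = list(n_pcs = 25, resolution = 0.25, k_neighbors = 20)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_config()]: a `run_config`; [write_config()]: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(structure(cfg, class = "run_config"))
}

#' @rdname read_config
#' @param cfg A `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  need <- c("seed", "movie", "piv", "classify", "counts", "qc", "hvg",
            "pca", "de", "score", "snn")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    abort(sprintf("config missing required field(s): %s",
                  paste(missing, collapse = ", ")))
  check_that(cfg$classify$low < cfg$classify$high,
             "classify thresholds must satisfy low < high")
  check_that(cfg$qc$min_genes <= cfg$qc$max_genes, "qc bounds out of order")
  cfg
}

#' Run the full behavioural-transcriptomics pipeline on synthetic data
#'
#' Executes simulate movie -> PIV -> speeds -> mover/non-mover
#' classification -> simulate plate counts -> QC -> variable genes -> PCA ->
#' marker clustering -> hurdle DE (basal cells, low-quality excluded) ->
#' signature sets -> injury time-course scoring -> SNN clustering, and
#' returns every stage output together with a manifest of seeds and content
#' checksums. Identical config (including seed) gives identical checksums.
#'
#' @param cfg A `run_config` from [default_config()] or [read_config()].
#' @return List of class `pipeline_run` with stage outputs and `manifest`
#'   (tibble: stage, checksum).
#' @export
run_pipeline <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  seed <- cfg$seed
  out <- list(config = cfg)
  record <- list()
  stage <- function(name, value) {
    record[[name]] <<- object_checksum(value)
    value
  }

  mc <- cfg$movie
  dt_hr <- mc$frame_interval / 3600
  field <- function(x, y, t) {
    fast <- x > mc$fov_um[1] / 2
    cbind(ifelse(fast, mc$fast_um_hr, mc$slow_um_hr) * dt_hr, 0 * y)
  }
  scn <- motion_scenario(field, n_nuclei = mc$n_nuclei,
                         nucleus_radius = mc$nucleus_radius,
                         frame_interval = mc$frame_interval,
                         n_frames = mc$n_frames, noise_sd = mc$noise_sd,
                         fov_um = mc$fov_um, seed = seed)
  movie <- stage("movie", simulate_tissue_movie(scn,
                                                grid_spacing = cfg$piv$grid_spacing))
  out$movie <- movie

  fields <- stage("piv", piv_movie(movie$stack, "nuclear",
                                   passes_um = cfg$piv$passes_um,
                                   grid_spacing = cfg$piv$grid_spacing,
                                   min_peak_ratio = cfg$piv$min_peak_ratio))
  out$fields <- fields
  # per-region mean speed across frame pairs, then classification
  speeds <- region_speeds(fields, dt = mc$frame_interval) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(speed_um_hr = mean(.data$speed_um_hr),
                     .groups = "drop")
  speeds$class <- classify_region(speeds$speed_um_hr,
                                  low = cfg$classify$low,
                                  high = cfg$classify$high)
  out$speeds <- stage("speeds", speeds)

  plate <- plate_scenario(seed = seed + 1L,
                          n_genes = cfg$counts$n_genes,
                          n_signature = cfg$counts$n_signature,
                          signature_lfc = cfg$counts$signature_lfc)
  out$plate_truth <- list(mover = attr(plate, "mover_genes"),
                          nonmover = attr(plate, "nonmover_genes"),
                          markers = attr(plate, "markers"))
  em <- stage("counts", simulate_counts(plate, units = "TPM"))$matrix
  out$plate_matrix <- em

  emq <- stage("qc", qc_filter(em, min_genes = cfg$qc$min_genes,
                               max_genes = cfg$qc$max_genes,
                               min_mapped = cfg$qc$min_mapped))
  out$qc <- emq
  hvg <- stage("hvg", select_variable_genes(
    emq, threshold = cfg$hvg$deviance_threshold))
  out$hvg <- hvg
  out$pca <- stage("pca", reduce_pca(emq, genes = union(
    hvg$genes, unlist(out$plate_truth$markers)), n_pcs = cfg$pca$n_pcs))

  markers <- unlist(out$plate_truth$markers, use.names = FALSE)
  labels <- stage("cluster", cluster_hierarchical(emq, markers))
  out$labels <- labels

  basal_cells <- labels$cell_id[labels$identity == "basal"]
  em_basal <- em_subset(emq, cells = basal_cells)
  de <- stage("de", hurdle_de(em_basal))
  out$de <- de
  sets <- stage("sets", signature_gene_sets(de, fdr_cut = cfg$de$fdr_cut))
  out$sets <- sets

  inj <- injury_scenario(seed = seed + 2L, n_genes = cfg$counts$n_genes)
  emi <- stage("injury_counts", simulate_counts(inj, units = "counts"))$matrix
  out$injury_matrix <- emi
  sc <- stage("scores", score_cells(
    emi, sets$mover, name = "mover",
    multiple = cfg$score$background_multiple))
  out$scores <- sc
  out$timepoint_tests <- stage("timepoint_tests",
    compare_scores(sc, group_col = "timepoint", reference = "uninjured"))

  em24 <- em_subset(emi, cells = emi$metadata$cell_id[
    emi$metadata$timepoint == "24"])
  snn <- stage("snn", snn_cluster(em24, n_pcs = cfg$snn$n_pcs,
                                  resolution = cfg$snn$resolution,
                                  k_neighbors = cfg$snn$k_neighbors,
                                  seed = seed + 3L))
  out$snn <- snn

  recovered <- sets$mover
  planted <- out$plate_truth$mover
  tp <- length(intersect(recovered, planted))
  out$recovery <- tibble(
    precision = if (length(recovered)) tp / length(recovered) else 0,
    recall = tp / length(planted))
  record[["recovery"]] <- object_checksum(out$recovery)

  out$manifest <- tibble(stage = names(record),
                         checksum = unlist(record, use.names = FALSE))
  class(out) <- "pipeline_run"
  out
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  mover regions: %d / %d grid vectors\n",
              sum(x$speeds$class == "mover"), nrow(x$speeds)))
  cat(sprintf("  DE genes (FDR < %.2f): %d mover, %d non-mover\n",
              x$config$de$fdr_cut, length(x$sets$mover),
              length(x$sets$nonmover)))
  cat(sprintf("  planted-set recovery: precision %.2f, recall %.2f\n",
              x$recovery$precision, x$recovery$recall))
  invisible(x)
}
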