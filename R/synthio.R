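#' @title Synthetic data with planted ground truth
#' @description Generators that emulate the two kinds of raw input the
#'   analysis consumes — time-lapse image stacks of regenerating epithelium
#'   and single-cell expression matrices — with every quantity the pipeline
#'   later estimates planted by construction, so recovery can be checked
#'   exactly.
#' @name synthio
NULL

# run code under a fixed RNG seed without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic tissue-motion movie
#'
#' @param field Function `(x, y, t) -> cbind(u, v)`: the displacement in um
#'   applied to a nucleus at position `(x, y)` um between frame `t` and
#'   `t + 1` (t = 1 is the first frame). Vectorised over positions.
#' @param n_nuclei Number of nuclei in the field of view.
#' @param nucleus_radius Nucleus radius in um (rendered as a Gaussian blob
#'   with sigma = radius / 2).
#' @param frame_interval Seconds between frames (default 600 s, i.e. one
#'   frame every 10 min).
#' @param n_frames Number of frames (>= 2).
#' @param noise_sd Additive Gaussian intensity noise.
#' @param fov_um Field of view `c(x, y)` in um.
#' @param pixel_size um per pixel.
#' @param height_fun Optional basement-membrane height `(x, y) -> um` above
#'   the deepest plane; when given together with `n_z > 1` an SHG-like sheet
#'   channel is rendered.
#' @param n_z Number of z planes.
#' @param z_step z spacing in um.
#' @param seed Integer RNG seed.
#' @return A validated `motion_scenario` list.
#' @export
motion_scenario <- function(field, n_nuclei = 150, nucleus_radius = 4,
                            frame_interval = 600, n_frames = 2,
                            noise_sd = 0.02, fov_um = c(96, 96),
                            pixel_size = 1, height_fun = NULL, n_z = 1L,
                            z_step = 2, seed = 1L) {
  check_that(n_frames >= 2, "n_frames must be >= 2")
  check_that(frame_interval > 0, "frame_interval must be positive")
  check_that(nucleus_radius > 0, "nucleus_radius must be positive")
  check_that(all(fov_um > 0) && pixel_size > 0 && n_z >= 1 && z_step > 0,
             "geometry parameters must be positive")
  structure(list(field = field, n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 fov_um = fov_um, pixel_size = pixel_size,
                 height_fun = height_fun, n_z = as.integer(n_z),
                 z_step = z_step, seed = as.integer(seed)),
            class = "motion_scenario")
}

# render Gaussian blobs at positions (um) into a ny x nx image;
# sigma_um and amplitude may be per-blob vectors
render_blobs <- function(pos, sigma_um, nx, ny, pixel_size, amplitude = 1) {
  img <- matrix(0, ny, nx)
  sigma_um <- rep_len(sigma_um, nrow(pos))
  amplitude <- rep_len(amplitude, nrow(pos))
  for (i in seq_len(nrow(pos))) {
    s <- sigma_um[i] / pixel_size
    r <- ceiling(3 * s)
    cx <- pos[i, 1] / pixel_size + 1   # 1-based pixel coordinates
    cy <- pos[i, 2] / pixel_size + 1
    x0 <- max(1, floor(cx - r)); x1 <- min(nx, ceiling(cx + r))
    y0 <- max(1, floor(cy - r)); y1 <- min(ny, ceiling(cy + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    gx <- exp(-((xs - cx)^2) / (2 * s^2))
    gy <- exp(-((ys - cy)^2) / (2 * s^2))
    img[ys, xs] <- img[ys, xs] + amplitude[i] * outer(gy, gx)
  }
  img
}

#' Simulate a time-lapse movie of moving nuclei over a curved membrane
#'
#' Nuclei are advected by the scenario's displacement field and rendered as
#' Gaussian blobs into a `nuclear` channel; when the scenario carries a
#' height function and more than one z plane, an `SHG` channel holds a bright
#' sheet at the planted membrane height. The returned ground truth carries
#' the planted displacement sampled on the 10 um analysis grid, the height
#' map on the pixel grid, and the per-frame nucleus positions.
#'
#' @param scn A [motion_scenario()].
#' @param grid_spacing um spacing of the ground-truth displacement grid.
#' @return A list with `stack` ([image_stack()]) and `truth` (list of
#'   `displacement` tibble, `height_map` matrix or NULL, `positions` tibble).
#' @export
simulate_tissue_movie <- function(scn, grid_spacing = 10) {
  check_that(inherits(scn, "motion_scenario"), "need a motion_scenario")
  nx <- round(scn$fov_um[1] / scn$pixel_size)
  ny <- round(scn$fov_um[2] / scn$pixel_size)
  check_that(nx > 0 && ny > 0, "field of view must span at least one pixel")
  with_local_seed(scn$seed, {
    pos <- cbind(runif(scn$n_nuclei, 0, scn$fov_um[1]),
                 runif(scn$n_nuclei, 0, scn$fov_um[2]))
    # nuclei vary in size and brightness, as in tissue
    sigma <- (scn$nucleus_radius / 2) * runif(scn$n_nuclei, 0.7, 1.3)
    bright <- runif(scn$n_nuclei, 0.5, 1.5)
    nuc <- array(0, dim = c(ny, nx, scn$n_z, scn$n_frames))
    positions <- vector("list", scn$n_frames)
    hm_px <- NULL
    z_of_nucleus <- rep(1L, scn$n_nuclei)
    if (!is.null(scn$height_fun) && scn$n_z > 1) {
      xs_um <- (seq_len(nx) - 1) * scn$pixel_size
      ys_um <- (seq_len(ny) - 1) * scn$pixel_size
      hm_px <- outer(ys_um, xs_um, function(y, x) scn$height_fun(x, y))
    }
    for (t in seq_len(scn$n_frames)) {
      if (is.null(hm_px)) {
        nuc[, , 1, t] <- render_blobs(pos, sigma, nx, ny, scn$pixel_size,
                                      amplitude = bright)
      } else {
        # nuclei sit a fixed offset above the membrane
        h <- scn$height_fun(pos[, 1], pos[, 2]) + 2 * scn$z_step
        zi <- pmin(pmax(round(h / scn$z_step) + 1L, 1L), scn$n_z)
        for (z in unique(zi)) {
          sel <- zi == z
          nuc[, , z, t] <- render_blobs(pos[sel, , drop = FALSE], sigma[sel],
                                        nx, ny, scn$pixel_size,
                                        amplitude = bright[sel])
        }
      }
      positions[[t]] <- tibble(frame = t, nucleus = seq_len(scn$n_nuclei),
                               x = pos[, 1], y = pos[, 2])
      if (t < scn$n_frames) {
        d <- scn$field(pos[, 1], pos[, 2], t)
        pos <- pos + d
      }
    }
    if (scn$noise_sd > 0)
      nuc <- nuc + array(rnorm(length(nuc), sd = scn$noise_sd), dim = dim(nuc))
    channels <- list(nuclear = nuc)
    if (!is.null(hm_px)) {
      shg <- array(0, dim = c(ny, nx, scn$n_z, scn$n_frames))
      z_um <- (seq_len(scn$n_z) - 1) * scn$z_step
      sheet <- vapply(z_um, function(z)
        exp(-((z - hm_px)^2) / (2 * scn$z_step^2)), hm_px)
      for (t in seq_len(scn$n_frames)) shg[, , , t] <- sheet
      if (scn$noise_sd > 0)
        shg <- shg + array(rnorm(length(shg), sd = scn$noise_sd),
                           dim = dim(shg))
      channels$SHG <- shg
    }
    stack <- image_stack(channels,
                         voxel_size = c(scn$pixel_size, scn$pixel_size,
                                        scn$z_step),
                         frame_interval = scn$frame_interval)
    gx <- seq(grid_spacing / 2, scn$fov_um[1] - grid_spacing / 2,
              by = grid_spacing)
    gy <- seq(grid_spacing / 2, scn$fov_um[2] - grid_spacing / 2,
              by = grid_spacing)
    grid <- expand.grid(x = gx, y = gy)
    disp <- purrr::map_dfr(seq_len(scn$n_frames - 1L), function(t) {
      d <- scn$field(grid$x, grid$y, t)
      tibble(t = t, x = grid$x, y = grid$y, u = d[, 1], v = d[, 2])
    })
    list(stack = stack,
         truth = list(displacement = disp, height_map = hm_px,
                      positions = dplyr::bind_rows(positions)))
  })
}

#' Simulate a high-speed movie of beating cilia
#'
#' Each pixel oscillates as `offset + amplitude * sin(2 pi f t + phase)` with
#' additive Gaussian noise, emulating surface recordings at 150 Hz over 200
#' frames.
#'
#' @param freq_map Matrix of per-pixel beat frequencies in Hz.
#' @param fs Sampling rate, Hz.
#' @param n_frames Number of frames.
#' @param amplitude Oscillation amplitude, scalar or matrix; 0 gives a
#'   constant-plus-noise movie.
#' @param offset Baseline intensity.
#' @param noise_sd Additive noise SD.
#' @param seed Integer RNG seed.
#' @return A list with `stack` (single-channel [image_stack()], one z plane)
#'   and `truth` (the frequency map).
#' @export
simulate_cilia_movie <- function(freq_map, fs = 150, n_frames = 200,
                                 amplitude = 1, offset = 2, noise_sd = 0.05,
                                 seed = 1L) {
  check_that(is.matrix(freq_map), "freq_map must be a matrix")
  check_that(all(freq_map > 0), "frequencies must be positive")
  if (any(freq_map >= fs / 2))
    abort("frequencies must lie below the Nyquist rate fs/2")
  check_that(n_frames >= 2 && fs > 0, "need fs > 0 and n_frames >= 2")
  ny <- nrow(freq_map); nx <- ncol(freq_map)
  if (is.matrix(amplitude))
    check_that(identical(dim(amplitude), dim(freq_map)),
               "amplitude map must match freq_map")
  with_local_seed(seed, {
    phase <- matrix(runif(ny * nx, 0, 2 * pi), ny, nx)
    movie <- array(0, dim = c(ny, nx, n_frames))
    tt <- (seq_len(n_frames) - 1) / fs
    for (k in seq_len(n_frames)) {
      movie[, , k] <- offset + amplitude * sin(2 * pi * freq_map * tt[k] +
                                                 phase)
    }
    if (noise_sd > 0)
      movie <- movie + array(rnorm(length(movie), sd = noise_sd),
                             dim = dim(movie))
    stack <- image_stack(list(surface = movie),
                         voxel_size = c(1, 1, 1),
                         frame_interval = 1 / fs)
    list(stack = stack, truth = list(freq_map = freq_map, fs = fs))
  })
}

#' Specify a synthetic single-cell count experiment
#'
#' Cells come in named groups (e.g. mover basal, non-mover basal, club,
#' low-quality); genes have log-normal baseline abundances; group-specific
#' log2 fold-changes are planted through `effects`; per-mouse random effects
#' and log-normal library sizes give counts the mouse-to-mouse and
#' depth-dependent dropout structure the downstream hurdle model and
#' matched-background scoring assume.
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of cells per group.
#' @param effects Tibble with columns `gene` (gene id or index), `group`,
#'   `lfc`: the gene's log2 fold-change in that group relative to baseline.
#' @param gene_names Optional character vector of gene ids.
#' @param n_mice Number of mice, assigned round-robin within groups.
#' @param mouse_sd SD of per-mouse, per-gene log-normal effects.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param libsize_meanlog Mean of log library size; scalar or named per
#'   group (a depressed value yields a low-quality group with few detected
#'   genes).
#' @param libsize_sdlog SD of log library size.
#' @param condition_map,timepoint_map Optional named maps group -> condition
#'   / timepoint label carried into metadata.
#' @param mapped_fraction_mean Mean mapped-read fraction; scalar or named
#'   per group.
#' @param seed Integer RNG seed.
#' @return A validated `count_scenario` list.
#' @export
count_scenario <- function(n_genes, group_sizes,
                           effects = tibble(gene = character(),
                                            group = character(),
                                            lfc = numeric()),
                           gene_names = NULL, n_mice = 3, mouse_sd = 0.15,
                           dispersion = 0.5,
                           libsize_meanlog = log(5e4), libsize_sdlog = 0.3,
                           condition_map = NULL, timepoint_map = NULL,
                           mapped_fraction_mean = 0.6, seed = 1L) {
  check_that(n_genes >= 2, "need at least two genes")
  check_that(length(group_sizes) >= 1 && all(group_sizes >= 1) &&
               !is.null(names(group_sizes)),
             "group_sizes must be a named vector of positive counts")
  effects <- as_tibble(effects)
  check_that(all(c("gene", "group", "lfc") %in% names(effects)),
             "effects needs columns gene, group, lfc")
  check_that(all(is.finite(effects$lfc)), "fold-changes must be finite")
  check_that(all(effects$group %in% names(group_sizes)),
             "effects reference unknown groups")
  if (is.null(gene_names))
    gene_names <- sprintf("g%04d", seq_len(n_genes))
  check_that(length(gene_names) == n_genes && !anyDuplicated(gene_names),
             "gene_names must be unique, one per gene")
  if (is.numeric(effects$gene)) effects$gene <- gene_names[effects$gene]
  check_that(all(effects$gene %in% gene_names), "effects reference unknown genes")
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = group_sizes, effects = effects,
                 gene_names = gene_names, n_mice = as.integer(n_mice),
                 mouse_sd = mouse_sd, dispersion = dispersion,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 condition_map = condition_map,
                 timepoint_map = timepoint_map,
                 mapped_fraction_mean = mapped_fraction_mean,
                 seed = as.integer(seed)),
            class = "count_scenario")
}

per_group <- function(x, groups) {
  if (is.null(names(x))) rep(x[1], length(groups))
  else {
    check_that(all(groups %in% names(x)), "per-group parameter missing a group")
    unname(x[groups])
  }
}

#' Simulate a single-cell count matrix with planted structure
#'
#' @param scn A [count_scenario()].
#' @param units `"counts"` (UMI-like) or `"TPM"` (plate-like; counts are
#'   depth-normalised to 1e6 per cell, effective gene lengths equal).
#' @return A list with `matrix` ([expr_matrix()]) and `truth` (planted
#'   effects, per-cell group labels, baseline means, library sizes).
#' @export
simulate_counts <- function(scn, units = c("counts", "TPM")) {
  units <- match.arg(units)
  check_that(inherits(scn, "count_scenario"), "need a count_scenario")
  with_local_seed(scn$seed, {
    groups <- rep(names(scn$group_sizes), scn$group_sizes)
    n_cells <- length(groups)
    cell_ids <- sprintf("c%04d", seq_len(n_cells))
    base <- rlnorm(scn$n_genes, meanlog = 0, sdlog = 1.4)
    base <- base / sum(base)
    lfc_mat <- matrix(0, scn$n_genes, length(scn$group_sizes),
                      dimnames = list(scn$gene_names, names(scn$group_sizes)))
    if (nrow(scn$effects))
      lfc_mat[cbind(match(scn$effects$gene, scn$gene_names),
                    match(scn$effects$group, colnames(lfc_mat)))] <-
        scn$effects$lfc
    mouse <- unlist(lapply(scn$group_sizes, function(k)
      rep_len(sprintf("m%d", seq_len(scn$n_mice)), k)), use.names = FALSE)
    mouse_eff <- matrix(rnorm(scn$n_genes * scn$n_mice, sd = scn$mouse_sd),
                        scn$n_genes, scn$n_mice,
                        dimnames = list(NULL, sprintf("m%d", seq_len(scn$n_mice))))
    libsize <- rlnorm(n_cells,
                      meanlog = per_group(scn$libsize_meanlog, groups),
                      sdlog = scn$libsize_sdlog)
    rel <- base * 2^(lfc_mat[, groups, drop = FALSE] +
                       mouse_eff[, mouse, drop = FALSE])
    rel <- sweep(rel, 2, colSums(rel), "/")
    mu <- sweep(rel, 2, libsize, "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / scn$dispersion),
                     nrow = scn$n_genes,
                     dimnames = list(scn$gene_names, cell_ids))
    mf_mean <- per_group(scn$mapped_fraction_mean, groups)
    mf <- rbeta(n_cells, mf_mean * 40, (1 - mf_mean) * 40)
    md <- tibble(cell_id = cell_ids, group = groups, mouse = mouse,
                 genes_detected = colSums(counts > 0), mapped_fraction = mf)
    if (!is.null(scn$condition_map))
      md$condition <- unname(scn$condition_map[groups])
    if (!is.null(scn$timepoint_map))
      md$timepoint <- unname(scn$timepoint_map[groups])
    em <- expr_matrix(counts, md, units = "counts")
    em$metadata <- md
    if (units == "TPM") em <- counts_to_tpm(em)
    list(matrix = em,
         truth = list(effects = scn$effects, group = groups,
                      baseline = setNames(base, scn$gene_names),
                      libsize = setNames(libsize, cell_ids)))
  })
}

#' Plate-based mover / non-mover scenario
#'
#' The study-condition default for the plate arm: mover and non-mover basal
#' cells with a planted directional signature (30 genes up in movers, 30 up
#' in non-movers, |log2FC| = 2), club cells with disjoint secretory markers,
#' and a low-depth low-quality group whose detected-gene distribution sits
#' well below the named clusters.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes.
#' @param n_per_group Cells per group.
#' @param n_signature Planted DE genes per direction.
#' @param signature_lfc Planted |log2 fold-change|.
#' @return A [count_scenario()]; its planted mover/non-mover genes are in
#'   `attr(, "mover_genes")` / `attr(, "nonmover_genes")` and the marker sets
#'   in `attr(, "markers")`.
#' @export
plate_scenario <- function(seed = 1L, n_genes = 2000,
                           n_per_group = c(mover_basal = 60,
                                           nonmover_basal = 60,
                                           club = 40, low_quality = 30),
                           n_signature = 30, signature_lfc = 2) {
  basal_markers <- behavex_basal_markers
  club_markers <- behavex_club_markers
  n_mark <- length(basal_markers)
  marker_lfc <- rep(c(4, 3, 2), length.out = n_mark)
  gene_names <- c(basal_markers, club_markers,
                  sprintf("g%04d", seq_len(n_genes - 2 * n_mark)))
  mover_genes <- sprintf("g%04d", 1:n_signature)
  nonmover_genes <- sprintf("g%04d", (n_signature + 1):(2 * n_signature))
  effects <- dplyr::bind_rows(
    tibble(gene = rep(basal_markers, 2),
           group = rep(c("mover_basal", "nonmover_basal"), each = n_mark),
           lfc = rep(marker_lfc, 2)),
    tibble(gene = club_markers, group = "club", lfc = marker_lfc),
    tibble(gene = mover_genes, group = "mover_basal", lfc = signature_lfc),
    tibble(gene = nonmover_genes, group = "nonmover_basal",
           lfc = signature_lfc))
  scn <- count_scenario(
    n_genes = n_genes, group_sizes = n_per_group, effects = effects,
    gene_names = gene_names,
    libsize_meanlog = c(mover_basal = log(8e4), nonmover_basal = log(8e4),
                        club = log(8e4), low_quality = log(4e3)),
    condition_map = c(mover_basal = "M", nonmover_basal = "NM",
                      club = "NM", low_quality = "NM"),
    mapped_fraction_mean = c(mover_basal = 0.6, nonmover_basal = 0.6,
                             club = 0.6, low_quality = 0.45),
    seed = seed)
  attr(scn, "mover_genes") <- mover_genes
  attr(scn, "nonmover_genes") <- nonmover_genes
  attr(scn, "markers") <- list(basal = basal_markers, club = club_markers)
  scn
}

#' Injury time-course scenario (UMI arm)
#'
#' Emulates a droplet-style re-analysis dataset: basal cells at 24, 48, 72
#' and 168 h post injury plus uninjured controls, with a planted mover
#' signature strongly elevated in a mover subpopulation at 24 h, partially
#' elevated at 48/72 h, and at baseline by 168 h; the non-mover signature
#' mirrors this. The 24 h population splits into mover-like and
#' non-mover-like halves so graph clustering has two planted communities.
#'
#' @param seed Integer RNG seed.
#' @param mover_genes,nonmover_genes Signature gene ids (defaults match
#'   [plate_scenario()]).
#' @param n_genes Number of genes.
#' @param n24 Cells per 24 h subpopulation.
#' @param n_other Cells per remaining timepoint.
#' @return A [count_scenario()] with `timepoint` metadata.
#' @export
injury_scenario <- function(seed = 1L,
                            mover_genes = sprintf("g%04d", 1:30),
                            nonmover_genes = sprintf("g%04d", 31:60),
                            n_genes = 2000, n24 = 300, n_other = 150) {
  gene_names <- c("Krt5", "Krt14", "Trp63", "Scgb1a1", "Scgb3a2", "Cyp2f2",
                  sprintf("g%04d", seq_len(n_genes - 6)))
  check_that(all(c(mover_genes, nonmover_genes) %in% gene_names),
             "signature genes must exist in the gene universe")
  sizes <- c(hpi24_m = n24, hpi24_nm = n24, hpi48 = n_other,
             hpi72 = n_other, hpi168 = n_other, uninjured = n_other)
  # the 24 h mover subpopulation carries the mover state (mover signature
  # up, non-mover signature down); the non-mover subpopulation stays at
  # baseline, as in the plate-arm contrast
  eff <- dplyr::bind_rows(
    tibble(gene = mover_genes, group = "hpi24_m", lfc = 2),
    tibble(gene = nonmover_genes, group = "hpi24_m", lfc = -1.5),
    tibble(gene = mover_genes, group = "hpi48", lfc = 0.8),
    tibble(gene = nonmover_genes, group = "hpi48", lfc = -0.5),
    tibble(gene = mover_genes, group = "hpi72", lfc = 0.5),
    tibble(gene = nonmover_genes, group = "hpi72", lfc = -0.3))
  count_scenario(
    n_genes = n_genes, group_sizes = sizes, effects = eff,
    gene_names = gene_names, libsize_meanlog = log(8e3),
    timepoint_map = c(hpi24_m = "24", hpi24_nm = "24", hpi48 = "48",
                      hpi72 = "72", hpi168 = "168", uninjured = "uninjured"),
    seed = seed)
}

# von Mises sampler (Best & Fisher rejection scheme); kappa >= 0, radians
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Simulate nucleus tracks with division events
#'
#' Each mother drifts with a random heading, carries an elongated ellipse
#' at a random orientation, and divides with the daughter-separation axis
#' drawn around the mother's long axis with von Mises angular jitter. The
#' movement heading is independent of the ellipse orientation, so movement-
#' axis angles relative to the division axis are uniform by construction.
#'
#' @param n_tracks Number of mother cells.
#' @param n_frames Frames of mother history before division.
#' @param jitter_deg Angular SD (deg) of the division-axis jitter around
#'   the long axis (converted to von Mises kappa = 1/sd_rad^2).
#' @param speed Mother drift per frame, um.
#' @param axis_ratio Mother ellipse major/minor ratio.
#' @param seed Integer RNG seed.
#' @return A track tibble suitable for [division_axis_alignment()].
#' @export
simulate_division_tracks <- function(n_tracks = 200, n_frames = 8,
                                     jitter_deg = 10, speed = 1.5,
                                     axis_ratio = 1.8, seed = 1L) {
  with_local_seed(seed, {
    kappa <- 1 / (jitter_deg * pi / 180)^2
    purrr::map_dfr(seq_len(n_tracks), function(i) {
      mid <- sprintf("cell%04d", i)
      orient <- runif(1, 0, 180)
      heading <- runif(1, 0, 2 * pi)
      start <- runif(2, 0, 200)
      frames <- seq_len(n_frames)
      xs <- start[1] + speed * cos(heading) * (frames - 1) +
        rnorm(n_frames, sd = 0.2)
      ys <- start[2] + speed * sin(heading) * (frames - 1) +
        rnorm(n_frames, sd = 0.2)
      mom <- tibble(cell_id = mid, frame = frames, x = xs, y = ys,
                    orientation = orient, major = 8 * axis_ratio, minor = 8,
                    parent_id = NA_character_)
      div_axis <- orient * pi / 180 +
        rvonmises(1, 0, kappa) + sample(c(0, pi), 1)
      sep <- 5
      centre <- c(xs[n_frames], ys[n_frames])
      kids <- tibble(
        cell_id = paste0(mid, c("a", "b")),
        frame = n_frames + 1L,
        x = centre[1] + c(1, -1) * sep / 2 * cos(div_axis),
        y = centre[2] + c(1, -1) * sep / 2 * sin(div_axis),
        orientation = runif(2, 0, 180), major = 9, minor = 8,
        parent_id = mid)
      dplyr::bind_rows(mom, kids)
    })
  })
}

#' Built-in airway epithelial marker panels
#'
#' Basal- and club-cell marker gene panels used by [plate_scenario()] and as
#' the identity defaults of [cluster_hierarchical()]: keratins and
#' hemidesmosome components for basal cells, secretoglobins and
#' detoxification enzymes for club cells.
#'
#' @format Character vectors of 25 gene symbols each.
#' @export
behavex_basal_markers <- c(
  "Krt5", "Krt14", "Trp63", "Aqp3", "Dapl1", "Perp", "Sfn", "Krt15",
  "Icam1", "Fxyd3", "Sdc1", "Col17a1", "Itgb4", "Itga6", "Lamb3",
  "Bcam", "Ngfr", "Pdpn", "Cav1", "Sparc", "Igfbp2", "S100a14",
  "Dst", "Krt17", "Emp1")

#' @rdname behavex_basal_markers
#' @export
behavex_club_markers <- c(
  "Scgb1a1", "Scgb3a2", "Cyp2f2", "Cbr2", "Ldhb", "Cldn10", "Hp",
  "Mgp", "Sec14l3", "Bpifa1", "Muc5b", "Sftpd", "Scnn1b", "Aldh1a1",
  "Gsta3", "Ephx1", "Cyp2b10", "Ces1d", "Gabrp", "Krt7", "Krt8",
  "Agr2", "Dnajc12", "Atp1b1", "Cckar")
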