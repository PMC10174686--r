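#' Construct a displacement field tibble
#'
#' @param x,y Grid positions in um.
#' @param u,v Displacements in um.
#' @param dt Time between the two frames in seconds.
#' @param grid_spacing Grid spacing in um.
#' @param valid Logical per-vector validity flag.
#' @param quality Correlation peak-to-second-peak ratio (NA when not from
#'   PIV).
#' @return A tibble of class `piv_field` with columns
#'   `x, y, u, v, valid, quality` and attributes `dt`, `grid_spacing`.
#' @export
displacement_field <- function(x, y, u, v, dt, grid_spacing = 10,
                               valid = NULL, quality = NA_real_) {
  check_that(dt > 0, "dt must be positive")
  valid <- valid %||% (is.finite(u) & is.finite(v))
  out <- tibble(x = x, y = y, u = u, v = v, valid = valid,
                quality = quality)
  attr(out, "dt") <- dt
  attr(out, "grid_spacing") <- grid_spacing
  class(out) <- c("piv_field", class(out))
  out
}

# cross-correlation peak between two equally sized windows, by zero-padded
# (linear) FFT correlation normalised by the overlap area so the estimate of
# the correlation at each lag is unbiased; search restricted to lags within
# half the window. Returns list(shift = c(dy, dx) incl. 3-point Gaussian
# sub-pixel fit, ratio = first-to-second peak ratio), or NULL for flat /
# peakless windows.
cc_peak <- function(A, B) {
  A <- A - mean(A); B <- B - mean(B)
  if (sd(A) < 1e-12 || sd(B) < 1e-12) return(NULL)
  w <- dim(A)
  P <- 2L * w
  Ap <- matrix(0, P[1], P[2]); Bp <- Ap
  Ap[seq_len(w[1]), seq_len(w[2])] <- A
  Bp[seq_len(w[1]), seq_len(w[2])] <- B
  cc <- Re(fft(fft(Bp) * Conj(fft(Ap)), inverse = TRUE)) / length(Ap)
  lag1 <- ifelse(seq_len(P[1]) - 1 >= P[1] / 2,
                 seq_len(P[1]) - 1 - P[1], seq_len(P[1]) - 1)
  lag2 <- ifelse(seq_len(P[2]) - 1 >= P[2] / 2,
                 seq_len(P[2]) - 1 - P[2], seq_len(P[2]) - 1)
  ov <- outer(w[1] - abs(lag1), w[2] - abs(lag2))
  ccn <- ifelse(ov > 0, cc * (w[1] * w[2]) / ov, -Inf)
  # quarter-window rule: valid displacements stay within w/4 of the
  # (offset-corrected) window centre, where the overlap is >= 75%
  mask <- outer(abs(lag1) <= w[1] / 4, abs(lag2) <= w[2] / 4)
  search <- ifelse(mask, ccn, -Inf)
  pk <- which(search == max(search), arr.ind = TRUE)[1, ]
  peak_val <- search[pk[1], pk[2]]
  if (!is.finite(peak_val) || peak_val <= 0) return(NULL)
  # second peak away from the first (exclusion radius scaled to the broad
  # correlation peaks of blob-like tissue texture)
  excl <- 3L
  ngb_i <- (pk[1] + (-excl:excl) - 1L) %% P[1] + 1L
  ngb_j <- (pk[2] + (-excl:excl) - 1L) %% P[2] + 1L
  cc2 <- search
  cc2[ngb_i, ngb_j] <- -Inf
  second <- max(cc2)
  ratio <- if (is.finite(second) && second > 0) peak_val / second else Inf
  # 3-point Gaussian (fallback parabolic) sub-pixel fit per axis
  sub <- function(cm, c0, cp) {
    if (!is.finite(cm) || !is.finite(cp)) return(0)
    if (cm > 0 && c0 > 0 && cp > 0) {
      den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
      if (abs(den) < 1e-12) return(0)
      (log(cm) - log(cp)) / den
    } else {
      den <- 2 * cm - 4 * c0 + 2 * cp
      if (abs(den) < 1e-12) return(0)
      (cm - cp) / den
    }
  }
  im <- (pk[1] - 2L) %% P[1] + 1L; ip <- pk[1] %% P[1] + 1L
  jm <- (pk[2] - 2L) %% P[2] + 1L; jp <- pk[2] %% P[2] + 1L
  dy <- lag1[pk[1]] + sub(ccn[im, pk[2]], peak_val, ccn[ip, pk[2]])
  dx <- lag2[pk[2]] + sub(ccn[pk[1], jm], peak_val, ccn[pk[1], jp])
  list(shift = c(dy, dx), ratio = ratio)
}

# replicate-pad a matrix by `p` on every side
pad_replicate <- function(m, p) {
  m2 <- m[c(rep(1, p), seq_len(nrow(m)), rep(nrow(m), p)), , drop = FALSE]
  m2[, c(rep(1, p), seq_len(ncol(m)), rep(ncol(m), p)), drop = FALSE]
}

#' Multi-pass PIV displacement between two frames
#'
#' Windowed direct-FFT cross-correlation with coarse-to-fine passes
#' (defaults 24, 16 and 10 um windows): each pass correlates a window of the
#' first frame centred on a 10 um grid point against a window of the second
#' frame offset by the previous pass's estimate, refining the displacement;
#' the final pass adds a 3-point Gaussian sub-pixel peak fit. Windows with
#' no texture, or whose correlation peak-to-second-peak ratio falls below
#' `min_peak_ratio`, are flagged invalid rather than zero.
#'
#' @param frame_a,frame_b Matrices of equal size (y by x).
#' @param pixel_size um per pixel.
#' @param dt Seconds between the frames.
#' @param passes_um Window edge lengths per pass, um (coarse to fine).
#' @param grid_spacing um spacing of the output vector grid.
#' @param min_peak_ratio Invalid-vector threshold on the ratio of the first
#'   to the second correlation peak.
#' @return A [displacement_field()] tibble in um.
#' @export
piv_displacement <- function(frame_a, frame_b, pixel_size = 1, dt = 600,
                             passes_um = c(24, 16, 10), grid_spacing = 10,
                             min_peak_ratio = 1.3) {
  check_that(identical(dim(frame_a), dim(frame_b)),
             "frames must have the same shape")
  check_that(dt > 0 && pixel_size > 0, "dt and pixel_size must be positive")
  w_px <- vapply(passes_um, function(w) {
    wp <- max(4L, 2L * round(w / pixel_size / 2))  # nearest even, >= 4 px
    as.integer(wp)
  }, integer(1))
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  fov_x <- nx * pixel_size; fov_y <- ny * pixel_size
  gx <- seq(grid_spacing / 2, fov_x - grid_spacing / 2, by = grid_spacing)
  gy <- seq(grid_spacing / 2, fov_y - grid_spacing / 2, by = grid_spacing)
  check_that(length(gx) > 0 && length(gy) > 0,
             "frames smaller than one grid cell")
  grid <- expand.grid(x = gx, y = gy)
  pad <- max(w_px)  # room for window halves plus shifted search windows
  A <- pad_replicate(frame_a, pad)
  B <- pad_replicate(frame_b, pad)
  n <- nrow(grid)
  u <- rep(0, n); v <- rep(0, n)
  valid <- rep(TRUE, n); quality <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    # 1-based padded pixel coordinates of the grid point
    cx <- grid$x[k] / pixel_size + 1 + pad
    cy <- grid$y[k] / pixel_size + 1 + pad
    est <- c(0, 0)  # (dy, dx) px
    ok <- TRUE; ratio <- NA_real_
    for (w in w_px) {
      half <- w / 2
      rows <- (round(cy) - half + 1):(round(cy) + half)
      cols <- (round(cx) - half + 1):(round(cx) + half)
      off <- round(est)
      rows_b <- rows + off[1]; cols_b <- cols + off[2]
      if (min(rows_b) < 1 || max(rows_b) > nrow(B) ||
          min(cols_b) < 1 || max(cols_b) > ncol(B)) { ok <- FALSE; break }
      pk <- cc_peak(A[rows, cols], B[rows_b, cols_b])
      if (is.null(pk)) { ok <- FALSE; break }
      est <- off + pk$shift
      ratio <- pk$ratio
    }
    if (!ok || is.na(ratio) || ratio < min_peak_ratio) {
      valid[k] <- FALSE; u[k] <- NA_real_; v[k] <- NA_real_
      quality[k] <- if (ok) ratio else NA_real_
      next
    }
    u[k] <- est[2] * pixel_size
    v[k] <- est[1] * pixel_size
    quality[k] <- ratio
  }
  displacement_field(grid$x, grid$y, u, v, dt = dt,
                     grid_spacing = grid_spacing, valid = valid,
                     quality = quality)
}

#' PIV over all consecutive frame pairs of a movie
#'
#' @param stack An [image_stack()] (single z plane used).
#' @param channel Channel to analyse.
#' @param z z plane index.
#' @param ... Passed to [piv_displacement()].
#' @return A tibble of stacked [displacement_field()]s with a `t` column
#'   (frame-pair index).
#' @export
piv_movie <- function(stack, channel = "nuclear", z = 1L, ...) {
  a <- stack_channel(stack, channel)
  d <- dim(a)
  check_that(d[4] >= 2, "need at least two frames")
  fields <- purrr::map_dfr(seq_len(d[4] - 1L), function(t) {
    f <- piv_displacement(a[, , z, t], a[, , z, t + 1L],
                          pixel_size = stack$voxel_size["x"],
                          dt = stack$frame_interval, ...)
    dplyr::mutate(f, t = t, .before = 1)
  })
  attr(fields, "dt") <- stack$frame_interval
  class(fields) <- c("piv_field", class(fields))
  fields
}

#' Per-region speeds from a displacement field
#'
#' Each grid vector covers one (grid_spacing x grid_spacing) um^2 region;
#' its speed is the displacement magnitude divided by the frame interval,
#' in um/hr. Invalid vectors are excluded.
#'
#' @param field A [displacement_field()].
#' @param dt Override the field's frame interval (seconds).
#' @return The field tibble restricted to valid vectors with a
#'   `speed_um_hr` column.
#' @export
region_speeds <- function(field, dt = NULL) {
  dt <- dt %||% attr(field, "dt")
  check_that(!is.null(dt) && dt > 0, "field must carry a positive dt")
  out <- dplyr::filter(field, .data$valid)
  if (nrow(out) == 0) abort("all vectors invalid")
  dplyr::mutate(out, speed_um_hr = sqrt(.data$u^2 + .data$v^2) / dt * 3600)
}

#' Mean tissue speed of a displacement field
#'
#' @param field A [displacement_field()].
#' @param dt Override the field's frame interval (seconds).
#' @return Global mean speed over valid vectors, um/hr.
#' @export
mean_speed <- function(field, dt = NULL) {
  mean(region_speeds(field, dt)$speed_um_hr)
}

#' Circular variance of displacement directions
#'
#' One minus the length of the mean resultant of the unit direction
#' vectors: 0 for perfectly aligned motion, approaching 1 for isotropic
#' motion. Zero-length and invalid vectors are excluded.
#'
#' @param field A [displacement_field()], or a numeric vector `u` when `v`
#'   is given.
#' @param v Optional y components when `field` is the x components.
#' @return Circular variance in `[0, 1]`.
#' @export
circular_variance <- function(field, v = NULL) {
  if (is.null(v)) {
    check_that(inherits(field, "piv_field") ||
                 all(c("u", "v") %in% names(field)),
               "need a displacement field or u and v vectors")
    keep <- if ("valid" %in% names(field)) field$valid else TRUE
    u <- field$u[keep]; v <- field$v[keep]
  } else {
    u <- field
  }
  len <- sqrt(u^2 + v^2)
  nz <- is.finite(len) & len > 0
  if (!any(nz)) abort("no valid non-zero vectors")
  ux <- u[nz] / len[nz]; uy <- v[nz] / len[nz]
  1 - sqrt(mean(ux)^2 + mean(uy)^2)
}

#' Classify region speed into mover / intermediate / non-mover
#'
#' Regions slower than `low` um/hr are non-movers, faster than `high` um/hr
#' movers; both bounds are strict, so a speed exactly at a threshold is
#' intermediate.
#'
#' @param speed Region speed(s), um/hr.
#' @param low,high Classification thresholds, um/hr (defaults 1.5 and 4).
#' @return Character vector: `"non_mover"`, `"intermediate"` or `"mover"`.
#' @export
classify_region <- function(speed, low = 1.5, high = 4) {
  check_that(all(speed >= 0, na.rm = TRUE), "speeds must be non-negative")
  dplyr::case_when(speed < low ~ "non_mover",
                   speed > high ~ "mover",
                   TRUE ~ "intermediate")
}

#' Screen a photoconverted region for mover behaviour
#'
#' A marked region qualifies as a mover when its displacement strictly
#' exceeds the threshold (default 50 um over the 18 h screening window);
#' the implied rate is reported but not enforced.
#'
#' @param displacement Net displacement of the region, um.
#' @param elapsed Hours since photoconversion.
#' @param threshold Displacement cut-off, um.
#' @return Tibble with `mover` (logical) and `rate_um_hr`.
#' @export
screen_photoconverted_region <- function(displacement, elapsed = 18,
                                         threshold = 50) {
  check_that(all(displacement >= 0), "displacement must be non-negative")
  check_that(all(elapsed > 0), "elapsed time must be positive")
  tibble(displacement_um = displacement, elapsed_hr = elapsed,
         mover = displacement > threshold,
         rate_um_hr = displacement / elapsed)
}

acute_axis_angle <- function(a_deg, b_deg) {
  d <- abs(a_deg - b_deg) %% 180
  pmin(d, 180 - d)
}

#' Division-axis geometry of tracked nuclei
#'
#' For each division event, compares the axis along which the daughters
#' separate with (i) the mother's interphase long axis and (ii) the
#' mother's net movement direction over the frames preceding division
#' (Hertwig's rule asks whether the long axis, not the movement axis,
#' predicts the division plane). Angles are acute, in degrees on [0, 90].
#'
#' @param tracks Tibble with columns `cell_id`, `frame`, `x`, `y` (um),
#'   `orientation` (ellipse major-axis angle, deg), `major`, `minor`
#'   (axis lengths, um) and `parent_id` (NA for founders).
#' @param window Frames before division over which the net movement
#'   direction is taken.
#' @param min_axis_ratio Ellipses rounder than this ratio give an
#'   undefined long-axis angle (NA, flagged).
#' @return Tibble, one row per division: mother id, division frame,
#'   `angle_long_axis`, `angle_movement_axis`, `axis_ratio`,
#'   `long_axis_defined`.
#' @export
division_axis_alignment <- function(tracks, window = 5,
                                    min_axis_ratio = 1.1) {
  need <- c("cell_id", "frame", "x", "y", "orientation", "major", "minor",
            "parent_id")
  check_that(all(need %in% names(tracks)), "track table missing columns")
  check_that(all(tracks$major > 0 & tracks$minor > 0),
             "axis lengths must be positive")
  mothers <- unique(tracks$parent_id[!is.na(tracks$parent_id)])
  if (!length(mothers)) abort("no division event in tracks")
  purrr::map_dfr(mothers, function(mid) {
    kids <- dplyr::filter(tracks, .data$parent_id == mid)
    kid_ids <- unique(kids$cell_id)
    if (length(kid_ids) != 2) abort(
      sprintf("mother %s must have exactly two daughters", mid))
    div_frame <- min(kids$frame)
    k1 <- dplyr::filter(kids, .data$cell_id == kid_ids[1],
                        .data$frame == div_frame)
    k2 <- dplyr::filter(kids, .data$cell_id == kid_ids[2],
                        .data$frame == div_frame)
    if (nrow(k1) != 1 || nrow(k2) != 1)
      abort("both daughters must be present at the first post-division frame")
    div_angle <- atan2(k2$y - k1$y, k2$x - k1$x) * 180 / pi
    mom <- dplyr::filter(tracks, .data$cell_id == mid,
                         .data$frame < div_frame) |>
      dplyr::arrange(.data$frame)
    check_that(nrow(mom) >= 1, "mother track missing before division")
    last <- mom[nrow(mom), ]
    ratio <- last$major / last$minor
    defined <- ratio >= min_axis_ratio
    first_idx <- max(1L, nrow(mom) - window)
    mv <- c(last$x - mom$x[first_idx], last$y - mom$y[first_idx])
    mv_angle <- if (sqrt(sum(mv^2)) < 1e-9) NA_real_
      else atan2(mv[2], mv[1]) * 180 / pi
    tibble(cell_id = mid, division_frame = div_frame,
           angle_long_axis = if (defined)
             acute_axis_angle(div_angle, last$orientation) else NA_real_,
           angle_movement_axis = if (is.na(mv_angle)) NA_real_
             else acute_axis_angle(div_angle, mv_angle),
           axis_ratio = ratio, long_axis_defined = defined)
  })
}
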