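#' Welch power spectral density of multiple traces
#'
#' Hann-windowed, overlapping-segment averaged periodograms, vectorised over
#' traces (one per column). Density scaling: summing the one-sided spectrum
#' times the bin width approximately recovers the trace variance.
#'
#' @param traces Numeric matrix, time in rows, one trace per column
#'   (de-meaned internally per segment).
#' @param fs Sampling rate, Hz.
#' @param segment_length Samples per segment.
#' @param overlap Fractional overlap between consecutive segments.
#' @return List with `freq` (Hz, one-sided, DC first) and `power`
#'   (bins x traces).
#' @export
welch_psd <- function(traces, fs, segment_length = 128, overlap = 0.5) {
  check_that(is.matrix(traces), "traces must be a matrix (time x traces)")
  n <- nrow(traces)
  check_that(fs > 0 && overlap >= 0 && overlap < 1, "bad fs or overlap")
  seg <- min(segment_length, n)
  step <- max(1L, round(seg * (1 - overlap)))
  starts <- seq(1L, n - seg + 1L, by = step)
  if (length(starts) < 2 && n >= seg && seg < n)
    starts <- unique(c(starts, n - seg + 1L))
  if (length(starts) < 2)
    warn("fewer than two segments: falling back to a single periodogram")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  norm <- fs * sum(w^2)
  nb <- floor(seg / 2) + 1L
  acc <- matrix(0, nb, ncol(traces))
  for (s in starts) {
    x <- traces[s:(s + seg - 1L), , drop = FALSE]
    x <- sweep(x, 2, colMeans(x))
    x <- x * w
    ft <- mvfft(x)
    p <- (Mod(ft[seq_len(nb), , drop = FALSE])^2) / norm
    # one-sided: double everything except DC (and Nyquist when seg even)
    dbl <- rep(2, nb); dbl[1] <- 1
    if (seg %% 2 == 0) dbl[nb] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nb) - 1L) * fs / seg,
       power = acc / length(starts))
}

#' Per-pixel ciliary beat frequency map
#'
#' Estimates, for every pixel of a high-speed surface movie, the power
#' spectral density of its intensity fluctuations by Welch's method and
#' takes the peak frequency. The DC bin and the first harmonic bin are
#' excluded from the peak search (slow drift); pixels whose peak power does
#' not rise above `k` times the median spectral power, or with no
#' fluctuation at all, are flagged invalid.
#'
#' @param movie An [image_stack()] (single z) or a 3D array (y, x, t).
#' @param fs Sampling rate, Hz (taken from the stack's frame interval when
#'   a stack is given).
#' @param segment_length,overlap Welch parameters.
#' @param k Validity threshold: peak power must exceed `k` x median power.
#' @return A tibble of class `spectral_map` with per-pixel `row`, `col`,
#'   `peak_frequency`, `peak_power`, `valid`, and attributes
#'   `frequency_resolution` and `map_dim`.
#' @export
cbf_map <- function(movie, fs = NULL, segment_length = 128, overlap = 0.5,
                    k = 5) {
  if (inherits(movie, "image_stack")) {
    fs <- fs %||% (1 / movie$frame_interval)
    a <- stack_channel(movie, names(movie$channels)[1])
    d <- dim(a)
    check_that(d[3] == 1, "cbf_map expects a single z plane")
    movie <- array(a, dim = c(d[1], d[2], d[4]))
  }
  check_that(length(dim(movie)) == 3, "movie must be (y, x, t)")
  check_that(!is.null(fs) && fs > 0, "sampling rate fs required")
  d <- dim(movie)
  traces <- matrix(movie, nrow = prod(d[1:2]), ncol = d[3])
  ps <- welch_psd(t(traces), fs, segment_length, overlap)
  nb <- length(ps$freq)
  search <- 3:nb  # exclude DC and the first bin
  pw <- ps$power[search, , drop = FALSE]
  pk_idx <- max.col(t(pw), ties.method = "first")
  peak_power <- pw[cbind(pk_idx, seq_len(ncol(pw)))]
  peak_freq <- ps$freq[search][pk_idx]
  med <- apply(ps$power, 2, median)
  valid <- peak_power > k * med & peak_power > 0
  out <- tibble(row = rep(seq_len(d[1]), d[2]),
                col = rep(seq_len(d[2]), each = d[1]),
                peak_frequency = peak_freq, peak_power = peak_power,
                valid = valid)
  attr(out, "frequency_resolution") <- ps$freq[2] - ps$freq[1]
  attr(out, "map_dim") <- d[1:2]
  attr(out, "fs") <- fs
  class(out) <- c("spectral_map", class(out))
  out
}

#' Mucociliary transport speed from bead tracks
#'
#' Net displacement divided by elapsed time per bead (transport is
#' directional, so path length is not used); the median across beads
#' summarises the field. Single-frame tracks are excluded with a warning.
#'
#' @param tracks Tibble with `bead_id`, `time_s`, `x`, `y` (um).
#' @return Tibble of per-bead speeds (um/s) with the across-bead median in
#'   attribute `median_speed`; also returned by [median_transport_speed()].
#' @export
bead_transport_speed <- function(tracks) {
  need <- c("bead_id", "time_s", "x", "y")
  check_that(all(need %in% names(tracks)), "track table missing columns")
  n_frames <- dplyr::count(tracks, .data$bead_id)
  bad <- n_frames$bead_id[n_frames$n < 2]
  if (length(bad)) {
    warn(sprintf("excluding %d single-frame track(s)", length(bad)))
    tracks <- dplyr::filter(tracks, !.data$bead_id %in% bad)
  }
  check_that(nrow(tracks) > 0, "no usable tracks")
  out <- tracks |>
    dplyr::group_by(.data$bead_id) |>
    dplyr::arrange(.data$time_s, .by_group = TRUE) |>
    dplyr::summarise(
      displacement_um = sqrt((dplyr::last(.data$x) - dplyr::first(.data$x))^2 +
                               (dplyr::last(.data$y) - dplyr::first(.data$y))^2),
      elapsed_s = dplyr::last(.data$time_s) - dplyr::first(.data$time_s),
      speed_um_s = .data$displacement_um / .data$elapsed_s,
      .groups = "drop")
  attr(out, "median_speed") <- median(out$speed_um_s)
  out
}

#' Median bead transport speed
#' @param tracks Bead track tibble (see [bead_transport_speed()]).
#' @return Median speed, um/s.
#' @export
median_transport_speed <- function(tracks) {
  attr(bead_transport_speed(tracks), "median_speed")
}
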