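#' Calibrated multi-channel image stack
#'
#' Container for 4D (y, x, z, t) fluorescence data with physical calibration.
#' Each channel is an array with dimensions `(y, x, z, t)`; purely planar
#' movies use a single z plane. Intensities are arbitrary units; positions are
#' converted to micrometres through `voxel_size`.
#'
#' @param channels Named list of numeric arrays, all the same dimension.
#'   Dimensions may be `(y, x)`, `(y, x, t)` (interpreted as one z plane) or
#'   `(y, x, z, t)`.
#' @param voxel_size Numeric length-3 vector `c(x, y, z)` in micrometres per
#'   voxel. For single-plane data the z step is still required (used when
#'   height maps are expressed in micrometres).
#' @param frame_interval Time between frames in seconds.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size, frame_interval) {
  check_that(is.list(channels) && length(channels) > 0 &&
               !is.null(names(channels)) && all(nzchar(names(channels))),
             "`channels` must be a non-empty named list")
  check_that(!anyDuplicated(names(channels)), "channel names must be unique")
  channels <- lapply(channels, function(a) {
    if (is.null(dim(a))) abort("each channel must be an array")
    d <- dim(a)
    if (length(d) == 2) dim(a) <- c(d, 1L, 1L)
    if (length(dim(a)) == 3) dim(a) <- c(dim(a)[1:2], 1L, dim(a)[3])
    check_that(length(dim(a)) == 4, "channel arrays must be 2D, 3D or 4D")
    a
  })
  d0 <- dim(channels[[1]])
  check_that(all(vapply(channels, function(a) identical(dim(a), d0), TRUE)),
             "all channels must share dimensions")
  check_that(length(voxel_size) == 3 && all(voxel_size > 0),
             "voxel_size must be three positive values (x, y, z) in um")
  check_that(frame_interval > 0, "frame_interval must be positive")
  structure(
    list(channels = channels,
         voxel_size = setNames(as.numeric(voxel_size), c("x", "y", "z")),
         frame_interval = as.numeric(frame_interval)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<image_stack> %d x %d px, %d z-plane(s), %d frame(s); channels: %s\n",
    d[2], d[1], d[3], d[4], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel %.3g x %.3g x %.3g um, frame interval %.3g s\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"],
              x$frame_interval))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

#' Extract one channel of an image stack
#'
#' @param stack An [image_stack()].
#' @param channel Channel name.
#' @param drop Drop unit z/t dimensions.
#' @return The channel array.
#' @export
stack_channel <- function(stack, channel, drop = FALSE) {
  check_that(channel %in% names(stack$channels),
             sprintf("channel '%s' not present", channel))
  a <- stack$channels[[channel]]
  if (drop) a <- drop(a)
  a
}

#' Write an image stack to multi-page TIFF
#'
#' Each channel goes to its own file (`<prefix>_<channel>.tif`), z and t
#' collapsed to pages (z fastest), with a JSON sidecar recording calibration
#' and page layout. Intensities are rescaled to `[0, 1]` for storage; the
#' scale is kept in the sidecar.
#'
#' @param stack An [image_stack()].
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_stack_tiff <- function(stack, prefix) {
  d <- dim(stack$channels[[1]])
  files <- character(0)
  meta <- list(voxel_size = as.list(stack$voxel_size),
               frame_interval = stack$frame_interval,
               dim = as.list(setNames(d, c("y", "x", "z", "t"))),
               channels = list())
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    lo <- min(a); hi <- max(a)
    scl <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(d[3] * d[4]), function(p) {
      zi <- (p - 1L) %% d[3] + 1L
      ti <- (p - 1L) %/% d[3] + 1L
      (a[, , zi, ti] - lo) / scl
    })
    f <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 16)
    files <- c(files, f)
    meta$channels[[ch]] <- list(file = basename(f), offset = lo, scale = scl)
  }
  sidecar <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(files, sidecar))
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param prefix Path prefix used at write time.
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  d <- unlist(meta$dim)
  channels <- lapply(meta$channels, function(chm) {
    pages <- tiff::readTIFF(file.path(dirname(prefix), chm$file), all = TRUE)
    a <- array(0, dim = d)
    for (p in seq_along(pages)) {
      zi <- (p - 1L) %% d[3] + 1L
      ti <- (p - 1L) %/% d[3] + 1L
      a[, , zi, ti] <- pages[[p]] * chm$scale + chm$offset
    }
    a
  })
  image_stack(channels,
              voxel_size = unlist(meta$voxel_size),
              frame_interval = meta$frame_interval)
}
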