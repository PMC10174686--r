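#' Estimate the basement-membrane height map from an SHG channel
#'
#' The collagen second-harmonic signal is maximal at the basement membrane,
#' so after smoothing the channel with a 3D Gaussian (typical sigma 10-25 um
#' in xy, 1-4 um in z) the per-(x, y) argmax over z locates the membrane.
#' The height is estimated independently for each time point because tissue
#' curvature changes over time; an optional temporal median over adjacent
#' frames can be enabled.
#'
#' @param stack An [image_stack()].
#' @param channel Channel holding the surface signal (default `"SHG"`).
#' @param sigma_xy,sigma_z Gaussian smoothing sigmas in um.
#' @param temporal_median Smooth each height map with the median over the
#'   +-1 adjacent frames (off by default).
#' @return An object of class `height_map`: list of per-frame matrices of z
#'   heights in um above the deepest plane (z = 0), with the smoothing
#'   parameters attached.
#' @export
estimate_height_map <- function(stack, channel = "SHG", sigma_xy = 15,
                                sigma_z = 2, temporal_median = FALSE) {
  a <- stack_channel(stack, channel)
  a[is.na(a)] <- 0  # flattened stacks carry NA fill outside the tissue
  d <- dim(a)
  check_that(d[3] >= 1, "need at least one z plane")
  if (max(abs(a)) == 0) abort("no surface signal: channel is all zero")
  sx <- sigma_xy / stack$voxel_size["x"]
  sy <- sigma_xy / stack$voxel_size["y"]
  sz <- if (d[3] > 1) sigma_z / stack$voxel_size["z"] else 0
  z_um <- (seq_len(d[3]) - 1) * stack$voxel_size["z"]
  maps <- lapply(seq_len(d[4]), function(t) {
    vol <- gauss_blur(array(a[, , , t], dim = d[1:3]), c(sy, sx, sz))
    idx <- apply(vol, c(1, 2), which.max)
    matrix(z_um[idx], d[1], d[2])
  })
  if (temporal_median && length(maps) > 1) {
    maps <- lapply(seq_along(maps), function(t) {
      win <- maps[max(1, t - 1):min(length(maps), t + 1)]
      apply(simplify2array(win), c(1, 2), median)
    })
  }
  structure(maps, class = "height_map",
            smoothing = c(sigma_xy = sigma_xy, sigma_z = sigma_z),
            z_step = unname(stack$voxel_size["z"]))
}

#' @export
print.height_map <- function(x, ...) {
  rng <- range(unlist(x))
  cat(sprintf("<height_map> %d frame(s), %d x %d px, range %.2f-%.2f um\n",
              length(x), nrow(x[[1]]), ncol(x[[1]]), rng[1], rng[2]))
  invisible(x)
}

#' Height map as a tibble
#' @param hm A `height_map`.
#' @return Tibble with columns `frame`, `row`, `col`, `z_um`.
#' @export
height_map_tbl <- function(hm) {
  purrr::map_dfr(seq_along(hm), function(t) {
    m <- hm[[t]]
    tibble(frame = t,
           row = rep(seq_len(nrow(m)), ncol(m)),
           col = rep(seq_len(ncol(m)), each = nrow(m)),
           z_um = as.vector(m))
  })
}

#' Flatten a stack by subtracting the membrane height
#'
#' Shifts every (x, y) column in z so the basement membrane comes to lie at
#' the deepest plane: output voxel `(x, y, z, t)` is input voxel
#' `(x, y, z + h(x, y), t)` with heights converted to planes through the z
#' step. Planes shifted outside the stack are filled with `fill`.
#'
#' @param stack An [image_stack()].
#' @param hm A `height_map` from [estimate_height_map()]; one map, or one
#'   per frame.
#' @param interpolate Use linear interpolation between z planes instead of
#'   the default nearest-plane integer shift.
#' @param fill Sentinel for out-of-range planes (default `NA`).
#' @return A flattened [image_stack()].
#' @export
flatten_stack <- function(stack, hm, interpolate = FALSE, fill = NA_real_) {
  d <- dim(stack$channels[[1]])
  check_that(inherits(hm, "height_map"), "hm must be a height_map")
  check_that(length(hm) %in% c(1L, d[4]),
             "height map must have 1 frame or one per stack frame")
  check_that(all(vapply(hm, function(m)
    identical(dim(m), d[1:2]), TRUE)),
    "height map extent must match the stack's (x, y) extent")
  z_step <- stack$voxel_size["z"]
  h_ref <- 0
  out <- stack
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    res <- array(fill, dim = d)
    for (t in seq_len(d[4])) {
      m <- hm[[min(t, length(hm))]]
      if (!interpolate) {
        shift <- round((m - h_ref) / z_step)
        for (s in unique(as.vector(shift))) {
          sel <- shift == s
          src <- seq_len(d[3]) + s
          ok <- src >= 1 & src <= d[3]
          for (z in which(ok)) {
            plane_src <- a[, , src[z], t]
            plane_dst <- res[, , z, t]
            plane_dst[sel] <- plane_src[sel]
            res[, , z, t] <- plane_dst
          }
        }
      } else {
        off <- (m - h_ref) / z_step
        lo <- floor(off); w <- off - lo
        vol_t <- array(a[, , , t], dim = d[1:3])
        for (z in seq_len(d[3])) {
          z0 <- z + lo; z1 <- z0 + 1
          p0 <- matrix(fill, d[1], d[2]); p1 <- p0
          ok0 <- z0 >= 1 & z0 <= d[3]; ok1 <- z1 >= 1 & z1 <= d[3]
          if (any(ok0)) p0[ok0] <- vol_t[cbind(row(m)[ok0], col(m)[ok0],
                                               z0[ok0])]
          if (any(ok1)) p1[ok1] <- vol_t[cbind(row(m)[ok1], col(m)[ok1],
                                               z1[ok1])]
          res[, , z, t] <- (1 - w) * p0 + w * p1
        }
      }
    }
    out$channels[[ch]] <- res
  }
  out
}
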