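#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rnorm runif rnbinom rlnorm rbeta rgamma fft mvfft var sd
#'   median quantile prcomp glm lm binomial wilcox.test p.adjust pchisq cor
#'   hclust cutree as.dist dist loess predict logLik coef complete.cases
#'   setNames na.omit aggregate
#' @importFrom utils head tail
NULL

# internal: stop unless condition holds
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# 1D Gaussian kernel, sigma in units of samples; radius 3 sigma
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# convolve a vector with a kernel using replicate padding (edge extension)
conv1_replicate <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(x)
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(r + 1L):(r + length(x))])
}

# separable Gaussian blur of a 2D or 3D array; sigmas in samples per dim
gauss_blur <- function(a, sigmas) {
  d <- dim(a)
  check_that(length(sigmas) == length(d), "one sigma per array dimension")
  out <- a
  for (ax in seq_along(d)) {
    if (sigmas[ax] <= 0) next
    k <- gauss_kernel(sigmas[ax])
    out <- apply_along(out, ax, function(v) conv1_replicate(v, k))
  }
  out
}

# apply f over 1D slices along axis `ax`, preserving shape
apply_along <- function(a, ax, f) {
  d <- dim(a)
  perm <- c(ax, seq_along(d)[-ax])
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[ax])
  m <- apply(m, 2, f)
  ap <- array(m, dim = d[perm])
  aperm(ap, order(perm))
}

# md5 of an R object via a temp file (stable across sessions for plain data)
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
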