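# Internal numerical helpers shared across modules.

# Population (divide-by-n) standard deviation; pinned because the mean+2SD
# background rule must be exactly reproducible at any n.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Discrete Gaussian kernel, truncated at 3 sigma, normalized to sum 1.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve an array along one dimension with edge replication. The
# convolution is a banded-matrix multiply so it runs in BLAS; at typical
# image sizes this is far cheaper than per-column filtering.
blur_along <- function(a, kernel, dimension) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  perm <- c(dimension, setdiff(seq_along(d), dimension))
  m <- matrix(aperm(a, perm), nrow = d[dimension])
  n <- nrow(m)
  r <- (length(kernel) - 1L) / 2L
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(n, r), , drop = FALSE])
  band <- matrix(0, n, n + 2L * r)
  idx <- cbind(rep(seq_len(n), each = length(kernel)),
               as.vector(outer(seq_along(kernel), seq_len(n) - 1L, `+`)))
  band[idx] <- rep(kernel, n)
  out <- array(band %*% mp, d[perm])
  aperm(out, order(perm))
}

# Separable Gaussian blur for 2D or 3D arrays. `sigma` is recycled per
# dimension, in units of voxels/pixels along that dimension.
gaussian_blur <- function(a, sigma) {
  d <- dim(a)
  sigma <- rep_len(sigma, length(d))
  for (i in seq_along(d)) {
    if (sigma[i] > 0 && d[i] > 1L) {
      a <- blur_along(a, gauss_kernel(sigma[i]), i)
    }
  }
  a
}

# Clip, round and coerce to 8-bit integer intensities.
quantize_8bit <- function(a) {
  a <- round(a)
  a[a < 0] <- 0
  a[a > 255] <- 255
  storage.mode(a) <- "integer"
  a
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vq <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
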