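# Discrete Gaussian (derivative) kernels, normalized so that polynomial
# inputs give exact derivatives: order 0 sums to 1; order 1 responds to a
# unit ramp with 1; order 2 responds to x^2 with 2.
gauss_kernel <- function(sigma_vox, order = 0L) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  if (order == 0L) {
    g / sum(g)
  } else if (order == 1L) {
    k <- x * g
    k / sum(x * k)
  } else if (order == 2L) {
    k <- (x^2 / sigma_vox^2 - 1) * g
    k <- k - sum(k) / length(k)
    k / (sum(x^2 * k) / 2)
  } else stop("order must be 0, 1 or 2")
}

# Separable Gaussian-derivative filter of a 3D array; sigma in mm,
# orders per axis; derivatives are with respect to physical mm.
gauss_filter3 <- function(data, spacing, sigma_mm, orders = c(0L, 0L, 0L)) {
  dims <- dim(data)
  out <- as.numeric(data)
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_mm / spacing[ax], orders[ax])
    if (orders[ax] > 0) k <- k / spacing[ax]^orders[ax]
    out <- .sep_correlate(out, dims, k, ax - 1L)
  }
  array(out, dim = dims)
}

#' Gaussian smoothing of a volume
#' @param volume a [coro_volume].
#' @param sigma_mm isotropic Gaussian standard deviation in mm.
#' @return A smoothed [coro_volume].
#' @export
gaussian_smooth <- function(volume, sigma_mm) {
  coro_volume(gauss_filter3(volume$data, volume$spacing, sigma_mm),
              spacing = volume$spacing, origin = volume$origin)
}

# Gaussian gradient magnitude (mm^-1 scaled HU), used for feature images.
gradient_magnitude <- function(volume, sigma_mm) {
  gx <- gauss_filter3(volume$data, volume$spacing, sigma_mm, c(1L, 0L, 0L))
  gy <- gauss_filter3(volume$data, volume$spacing, sigma_mm, c(0L, 1L, 0L))
  gz <- gauss_filter3(volume$data, volume$spacing, sigma_mm, c(0L, 0L, 1L))
  sqrt(gx^2 + gy^2 + gz^2)
}

# central-difference gradient (per mm) of a plain array
central_gradient <- function(data, spacing) {
  dims <- dim(data)
  v <- as.numeric(data)
  lapply(1:3, function(ax) {
    k <- c(-0.5, 0, 0.5) / spacing[ax]
    array(.sep_correlate(v, dims, k, ax - 1L), dim = dims)
  })
}
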