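#' Parameters for the multiscale Frangi vesselness filter
#'
#' Defaults follow the original Frangi formulation: plate/line sensitivity
#' \code{alpha} 0.5, blob sensitivity \code{beta} 0.5, and a data-adaptive
#' structureness constant \code{c} (half the maximum Hessian Frobenius norm
#' per scale, so Hounsfield scaling cancels). Scales default to 0.5--2.5 mm,
#' covering coronary calibers of 2 mm and above.
#'
#' @param scales Gaussian scales in mm (all > 0).
#' @param alpha,beta dimensionless sensitivities (> 0).
#' @param c structureness sensitivity in HU units; NA for data-adaptive.
#' @param bright_on_dark polarity: TRUE enhances bright tubes on dark.
#' @return A \code{coro_vesselness_params} list.
#' @export
vesselness_params <- function(scales = c(0.5, 1.0, 1.5, 2.0, 2.5),
                              alpha = 0.5, beta = 0.5, c = NA,
                              bright_on_dark = TRUE) {
  if (length(scales) == 0 || any(scales <= 0))
    stop("scales must be non-empty and positive")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (!is.na(c) && c <= 0) stop("c must be > 0 (or NA for data-adaptive)")
  structure(list(scales = as.numeric(scales), alpha = alpha, beta = beta,
                 c = c, bright_on_dark = isTRUE(bright_on_dark)),
            class = "coro_vesselness_params")
}

#' Multiscale Hessian (Frangi) vesselness filter
#'
#' Enhances tube-like structures: per voxel and scale, the Hessian of the
#' Gaussian-smoothed image is formed with gamma-normalized (gamma = 1, i.e.
#' sigma^2-scaled) second derivatives, its eigenvalues are sorted by absolute
#' value, and the Frangi line measure is evaluated; the output is the maximum
#' over scales, forced to zero where the second/third eigenvalues have the
#' wrong sign for the requested polarity.
#'
#' @param volume a [coro_volume] (HU values used directly).
#' @param params a [vesselness_params].
#' @return A \code{coro_vesselness} object (values in [0,1], same grid),
#'   with per-voxel \code{scale_of_max} (mm).
#' @export
frangi_vesselness <- function(volume, params = vesselness_params()) {
  stopifnot(inherits(volume, "coro_volume"))
  dims <- dim(volume$data)
  if (max(params$scales) < max(volume$spacing))
    stop("at least one scale must be >= the maximum voxel spacing")
  if (any(dims - 2 * ceiling(max(params$scales) / volume$spacing) < 2))
    stop("volume too small along one axis at the largest scale")
  sp <- volume$spacing
  best <- array(0, dim = dims)
  sbest <- array(NA_real_, dim = dims)
  hessians <- function(s) {
    g <- s^2                      # gamma-normalization, gamma = 1
    list(xx = g * gauss_filter3(volume$data, sp, s, c(2L, 0L, 0L)),
         yy = g * gauss_filter3(volume$data, sp, s, c(0L, 2L, 0L)),
         zz = g * gauss_filter3(volume$data, sp, s, c(0L, 0L, 2L)),
         xy = g * gauss_filter3(volume$data, sp, s, c(1L, 1L, 0L)),
         xz = g * gauss_filter3(volume$data, sp, s, c(1L, 0L, 1L)),
         yz = g * gauss_filter3(volume$data, sp, s, c(0L, 1L, 1L)))
  }
  cval <- params$c
  if (is.na(cval)) {
    # data-adaptive structureness constant, fixed across scales so that the
    # per-voxel argmax over scales is meaningful: half the maximum Hessian
    # Frobenius norm over the volume and over all scales
    cval <- max(vapply(params$scales, function(s) {
      d2 <- hessians(s)
      .frangi_combine(d2$xx, d2$yy, d2$zz, d2$xy, d2$xz, d2$yz,
                      params$alpha, params$beta, -1,
                      params$bright_on_dark, FALSE)$c_used
    }, 0.0))
  }
  for (s in params$scales) {
    d2 <- hessians(s)
    res <- .frangi_combine(d2$xx, d2$yy, d2$zz, d2$xy, d2$xz, d2$yz,
                           params$alpha, params$beta, cval,
                           params$bright_on_dark, FALSE)
    r <- array(res$response, dim = dims)
    upd <- r > best
    best[upd] <- r[upd]
    sbest[upd] <- s
  }
  out <- structure(list(data = best, spacing = sp, origin = volume$origin,
                        scale_of_max = sbest),
                   class = c("coro_vesselness", "coro_volume"))
  out
}

#' Hessian eigenvalues at a single voxel
#'
#' Second-derivative analysis at one lattice point and one Gaussian scale,
#' returning the eigenvalues sorted by absolute value. This is the public
#' oracle for [frangi_vesselness]: eigen-decomposition here uses base R's
#' \code{eigen}, independent of the filter's closed-form path. Points within
#' one sigma of the border are computed with mirrored boundaries and flagged
#' via \code{attr(x, "valid") = FALSE}.
#'
#' @param volume a [coro_volume].
#' @param point integer 0-based lattice index (x, y, z).
#' @param sigma Gaussian scale in mm.
#' @return numeric length-3 eigenvalues (|l1| <= |l2| <= |l3|), HU/mm^2.
#' @export
hessian_eigenvalues_at <- function(volume, point, sigma) {
  dims <- dim(volume$data)
  point <- as.integer(round(point))
  if (any(point < 0) || any(point >= dims))
    stop("point must be an interior lattice index")
  sp <- volume$spacing
  rad <- ceiling(4 * sigma / sp) + 1L
  lo <- pmax(point - 2L * rad, 0L)
  hi <- pmin(point + 2L * rad, dims - 1L)
  patch <- volume$data[(lo[1] + 1):(hi[1] + 1),
                       (lo[2] + 1):(hi[2] + 1),
                       (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  ctr <- point - lo + 1L
  H <- matrix(0, 3, 3)
  ords <- list(c(2L, 0L, 0L), c(0L, 2L, 0L), c(0L, 0L, 2L),
               c(1L, 1L, 0L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  pos <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (k in seq_along(ords)) {
    d <- gauss_filter3(patch, sp, sigma, ords[[k]])
    H[pos[[k]][1], pos[[k]][2]] <- d[ctr[1], ctr[2], ctr[3]]
    H[pos[[k]][2], pos[[k]][1]] <- H[pos[[k]][1], pos[[k]][2]]
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[order(abs(ev))]
  valid <- all(point - rad >= 0) && all(point + rad <= dims - 1)
  structure(ev, valid = valid)
}
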