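#' Level-set evolution parameters
#'
#' Constants of the edge-based geodesic evolution. The sigmoid center
#' \code{sigmoid_beta} defaults to data-adaptive (a quantile of the gradient
#' magnitude in a one-sided shell just outside the initial contour); the
#' width \code{sigmoid_alpha} defaults to \code{beta * alpha_scale}. The
#' propagation weight's sign sets the direction: positive evolves outward
#' (lumen, S3), negative inward (vessel, S4). The pipeline's outer-wall
#' stage uses propagation only (no advection) with \code{beta_quantile}
#' 0.5, because the outer boundary is a gradient shoulder, not a peak; see
#' the methods vignette.
#'
#' @param gradient_sigma Gaussian derivative scale in mm for the gradient
#'   image (default 0.5 mm).
#' @param sigmoid_alpha sigmoid width, HU/mm; NA for beta * alpha_scale.
#' @param sigmoid_beta sigmoid center, HU/mm; NA for data-adaptive.
#' @param beta_quantile quantile of the outside-shell gradient magnitude
#'   used for the data-adaptive center: 0.9 targets a distinct edge peak
#'   (lumen); 0.5 targets the background level so the front stops where the
#'   gradient first rises above it -- the right behaviour for the outer wall,
#'   whose boundary is a gradient shoulder rather than a peak.
#' @param alpha_scale sigmoid width as a fraction of beta (when
#'   \code{sigmoid_alpha} is NA).
#' @param propagation_weight dimensionless; sign sets outward/inward.
#' @param curvature_weight dimensionless, >= 0.
#' @param advection_weight dimensionless.
#' @param max_iterations iteration cap.
#' @param rms_convergence RMS phi-change (mm) per iteration below which the
#'   evolution stops.
#' @param reinit_every iterations between signed-distance reinitializations.
#' @param band_mm narrow-band half-width in mm; NA for 6 x min spacing.
#' @return A \code{coro_ls_params} list.
#' @export
levelset_params <- function(gradient_sigma = 0.5, sigmoid_alpha = NA,
                            sigmoid_beta = NA, beta_quantile = 0.9,
                            alpha_scale = 0.2, propagation_weight = 0.5,
                            curvature_weight = 0.4, advection_weight = 2.0,
                            max_iterations = 500, rms_convergence = 1e-3,
                            reinit_every = 20, band_mm = NA) {
  if (gradient_sigma <= 0) stop("gradient_sigma must be > 0")
  if (max_iterations <= 0) stop("max_iterations must be > 0")
  if (rms_convergence <= 0) stop("rms_convergence must be > 0")
  if (curvature_weight < 0) stop("curvature_weight must be >= 0")
  structure(list(gradient_sigma = gradient_sigma,
                 sigmoid_alpha = sigmoid_alpha, sigmoid_beta = sigmoid_beta,
                 beta_quantile = beta_quantile, alpha_scale = alpha_scale,
                 propagation_weight = propagation_weight,
                 curvature_weight = curvature_weight,
                 advection_weight = advection_weight,
                 max_iterations = as.integer(max_iterations),
                 rms_convergence = rms_convergence,
                 reinit_every = as.integer(reinit_every),
                 band_mm = band_mm),
            class = "coro_ls_params")
}

#' Edge-stopping feature (speed) image
#'
#' The feature image is the sigmoid of the Gaussian gradient-magnitude image:
#' \code{1 / (1 + exp((g - beta) / alpha))}, oriented so homogeneous regions
#' map to ~1 (fast propagation) and strong edges to ~0 (stop). When
#' \code{sigmoid_beta} is NA it is set data-adaptively to the 90th percentile
#' of the gradient magnitude within a ~2-voxel shell around the initial
#' contour (if given), else over the positive gradients of the whole volume.
#'
#' @param volume a [coro_volume].
#' @param params a [levelset_params].
#' @param init optional initial-contour [coro_mask] used for the adaptive
#'   sigmoid center.
#' @return A \code{coro_feature} volume with values in [0, 1]; the constants
#'   used are stored in attributes \code{beta_used} / \code{alpha_used}.
#' @export
compute_feature_image <- function(volume, params = levelset_params(),
                                  init = NULL) {
  g <- gradient_magnitude(volume, params$gradient_sigma)
  beta <- params$sigmoid_beta
  if (is.na(beta)) {
    if (!is.null(init)) {
      stopifnot_same_grid(volume, init)
      phi <- array(.signed_distance_cpp(as.logical(init$data), dim(g),
                                        volume$spacing), dim = dim(g))
      # one-sided shell just outside the initial contour: that is where the
      # stopping edge lives for both the outward (lumen) and inward (vessel)
      # evolutions; a two-sided shell on a thin wall would pick up the much
      # stronger lumen edge and de-sensitize the outer-wall sigmoid
      shell <- phi > 0 & phi <= 3 * min(volume$spacing)
      beta <- stats::quantile(g[shell], params$beta_quantile, names = FALSE)
    } else {
      gz <- g[g > 0]
      beta <- if (length(gz))
        stats::quantile(gz, params$beta_quantile, names = FALSE) else 1
    }
    if (beta <= 0) beta <- max(g, 1e-6)
  }
  alpha <- params$sigmoid_alpha
  if (is.na(alpha)) alpha <- beta * params$alpha_scale
  if (alpha == 0) stop("sigmoid_alpha must be nonzero")
  f <- 1 / (1 + exp((g - beta) / alpha))
  structure(list(data = f, spacing = volume$spacing, origin = volume$origin),
            class = c("coro_feature", "coro_volume"),
            beta_used = beta, alpha_used = alpha,
            gradient_sigma = params$gradient_sigma)
}

#' Evolve an edge-based level set from an initial mask
#'
#' Initializes a signed-distance function from the mask (negative inside) and
#' evolves it with feature-weighted propagation, feature-weighted curvature
#' regularization, and advection toward feature minima, using an upwind
#' narrow-band scheme with CFL-bounded time steps and periodic
#' signed-distance reinitialization. Evolution stops at the RMS convergence
#' threshold or at \code{max_iterations} (then the result carries a
#' non-convergence flag, not an error). Voxels with phi exactly 0 are
#' foreground.
#'
#' @param initial non-empty initial [coro_mask].
#' @param feature a [compute_feature_image] result on the same grid.
#' @param params a [levelset_params]; the sign of \code{propagation_weight}
#'   selects outward (+, lumen) or inward (-, vessel) evolution.
#' @return A [coro_mask] with attributes \code{iterations}, \code{rms},
#'   \code{converged}.
#' @export
evolve_level_set <- function(initial, feature, params = levelset_params()) {
  stopifnot_same_grid(initial, feature)
  if (!any(initial$data)) stop("initial mask is empty")
  dims <- dim(initial$data)
  sp <- initial$spacing
  phi0 <- .signed_distance_cpp(as.logical(initial$data), dims, sp)
  gf <- central_gradient(feature$data, sp)
  band <- params$band_mm
  if (is.na(band)) band <- 6 * min(sp)
  res <- .evolve_levelset_cpp(phi0, as.numeric(feature$data),
                              as.numeric(gf[[1]]), as.numeric(gf[[2]]),
                              as.numeric(gf[[3]]),
                              dims, sp,
                              params$propagation_weight,
                              params$curvature_weight,
                              params$advection_weight,
                              params$max_iterations,
                              params$rms_convergence,
                              params$reinit_every, band)
  m <- array(res$phi <= 0, dim = dims)
  out <- coro_mask(m, spacing = sp, origin = initial$origin)
  attr(out, "iterations") <- res$iterations
  attr(out, "rms") <- res$rms
  attr(out, "converged") <- res$converged
  if (!res$converged)
    attr(out, "warning") <- "level set did not converge within max_iterations"
  out
}

#' Join lumen and vessel segmentations into a wall segmentation
#'
#' Enforces containment (vessel := vessel union lumen) and derives the wall
#' as the set difference, voxel-exact: wall = vessel AND NOT lumen.
#'
#' @param lumen_final,vessel_final [coro_mask]s on one grid.
#' @return A \code{coro_wallseg} list with \code{lumen}, \code{vessel},
#'   \code{wall} masks.
#' @export
segment_wall <- function(lumen_final, vessel_final) {
  stopifnot_same_grid(lumen_final, vessel_final)
  vessel <- vessel_final$data | lumen_final$data
  wall <- vessel & !lumen_final$data
  structure(list(
    lumen = lumen_final,
    vessel = coro_mask(vessel, spacing = lumen_final$spacing,
                       origin = lumen_final$origin),
    wall = coro_mask(wall, spacing = lumen_final$spacing,
                     origin = lumen_final$origin)),
    class = "coro_wallseg")
}
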