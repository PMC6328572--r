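#' Hounsfield-unit model for phantom tissue classes
#'
#' Defaults follow standard CT tissue ranges: contrast-filled lumen 400 HU,
#' wall and soft plaque 50 HU, calcified plaque 800 HU, perivascular fat
#' -80 HU (fat is negative by definition), myocardium 40 HU (close to the
#' wall: outer contrast is genuinely low), lung/background -800 HU.
#'
#' @param lumen_hu,wall_hu,soft_plaque_hu,calcified_plaque_hu,fat_hu,myocardium_hu,background_hu
#'   HU levels per class.
#' @return A \code{coro_hu_model} list.
#' @export
hu_model <- function(lumen_hu = 400, wall_hu = 50, soft_plaque_hu = 50,
                     calcified_plaque_hu = 800, fat_hu = -80,
                     myocardium_hu = 40, background_hu = -800) {
  if (fat_hu >= 0) stop("fat_hu must be negative")
  if (lumen_hu <= wall_hu) stop("lumen_hu must exceed wall_hu")
  if (calcified_plaque_hu <= lumen_hu)
    stop("calcified_plaque_hu must exceed lumen_hu")
  structure(list(lumen_hu = lumen_hu, wall_hu = wall_hu,
                 soft_plaque_hu = soft_plaque_hu,
                 calcified_plaque_hu = calcified_plaque_hu, fat_hu = fat_hu,
                 myocardium_hu = myocardium_hu, background_hu = background_hu),
            class = "coro_hu_model")
}

#' A focal plaque on the phantom vessel
#'
#' The plaque narrows the lumen by \code{lumen_narrowing_fraction} and
#' thickens the wall by up to \code{max_wall_thickening}, both modulated by a
#' smooth raised-cosine bump over \code{[start_arc_length, start_arc_length
#' + length]}.
#'
#' @param start_arc_length mm along the centerline.
#' @param length mm (> 0).
#' @param type "soft", "calcified" or "mixed".
#' @param max_wall_thickening mm added to the outer radius at the bump peak.
#' @param lumen_narrowing_fraction in [0, 1): fractional lumen radius loss at
#'   the bump peak.
#' @return A \code{coro_plaque_spec} list.
#' @export
plaque_spec <- function(start_arc_length, length,
                        type = c("soft", "calcified", "mixed"),
                        max_wall_thickening = 1.0,
                        lumen_narrowing_fraction = 0.5) {
  type <- match.arg(type)
  if (length <= 0) stop("plaque length must be > 0")
  if (lumen_narrowing_fraction < 0 || lumen_narrowing_fraction >= 1)
    stop("lumen_narrowing_fraction must be in [0, 1)")
  structure(list(start_arc_length = start_arc_length, length = length,
                 type = type, max_wall_thickening = max_wall_thickening,
                 lumen_narrowing_fraction = lumen_narrowing_fraction),
            class = "coro_plaque_spec")
}

#' Parametric centerline curves for phantoms
#'
#' @param length line length in mm.
#' @return A curve description used by [phantom_spec].
#' @export
curve_line <- function(length = 35) {
  structure(list(type = "line", length = length), class = "coro_curve")
}

#' @rdname curve_line
#' @param radius ring radius in mm (arc/helix).
#' @param angle subtended angle in radians (arc).
#' @export
curve_arc <- function(radius = 20, angle = pi / 2) {
  structure(list(type = "arc", radius = radius, angle = angle),
            class = "coro_curve")
}

#' @rdname curve_line
#' @param pitch helix pitch parameter c in mm (z = c * t).
#' @param turns number of turns.
#' @export
curve_helix <- function(radius = 10, pitch = 3, turns = 1) {
  structure(list(type = "helix", radius = radius, pitch = pitch,
                 turns = turns), class = "coro_curve")
}

# densely sampled curve points centered at `center`, plus arc length
curve_points <- function(curve, center, step = 0.1) {
  if (curve$type == "line") {
    s <- seq(0, curve$length, by = step)
    pts <- cbind(center[1], center[2], center[3] - curve$length / 2 + s)
  } else if (curve$type == "arc") {
    L <- curve$radius * curve$angle
    s <- seq(0, L, by = step)
    th <- s / curve$radius
    # ring center placed so the arc chord is centered in the volume
    thc <- curve$angle / 2
    pts <- cbind(center[1] + curve$radius * (cos(th - thc) - 1) +
                   curve$radius * (1 - cos(thc)) / 2,
                 center[2],
                 center[3] + curve$radius * sin(th - thc))
  } else if (curve$type == "helix") {
    c0 <- curve$pitch
    tmax <- 2 * pi * curve$turns
    L <- tmax * sqrt(curve$radius^2 + c0^2)
    s <- seq(0, L, by = step)
    t <- s / sqrt(curve$radius^2 + c0^2)
    pts <- cbind(center[1] + curve$radius * cos(t),
                 center[2] + curve$radius * sin(t),
                 center[3] + c0 * (t - tmax / 2))
  } else stop("unknown curve type")
  list(points = pts, arclen = s)
}

#' Full phantom specification
#'
#' Defines the study conditions a generated CTA phantom emulates: a single
#' vessel along a parametric curve, a healthy wall of 0.75 mm around a
#' 1.5 mm lumen, optional plaques, a perivascular fat sheath (the typical
#' coronary environment), myocardium beyond, Gaussian noise, and optional
#' motion blur over an arc-length window.
#'
#' @param centerline_curve a [curve_line], [curve_arc] or [curve_helix].
#' @param lumen_radius scalar mm or function(s mm) -> mm.
#' @param wall_thickness scalar mm or function(s) -> mm (outer radius =
#'   lumen radius + wall thickness before plaque thickening).
#' @param plaques list of [plaque_spec]s.
#' @param hu a [hu_model].
#' @param noise_sigma additive Gaussian noise standard deviation in HU
#'   (default 20, typical CCTA noise).
#' @param motion_blur NULL or list(window = c(s0, s1) mm, sigma = mm,
#'   transition = mm) describing a local anisotropic blur emulating a motion
#'   artifact.
#' @param fat_sheath logical: surround the wall with a fat ring.
#' @param fat_thickness mm of the fat ring.
#' @param seed integer RNG seed for the noise.
#' @return A \code{coro_phantom_spec} list.
#' @export
phantom_spec <- function(centerline_curve = curve_line(35),
                         lumen_radius = 1.5, wall_thickness = 0.75,
                         plaques = list(), hu = hu_model(),
                         noise_sigma = 20, motion_blur = NULL,
                         fat_sheath = TRUE, fat_thickness = 1.5,
                         seed = 1L) {
  if (inherits(plaques, "coro_plaque_spec")) plaques <- list(plaques)
  structure(list(centerline_curve = centerline_curve,
                 lumen_radius = lumen_radius,
                 wall_thickness = wall_thickness, plaques = plaques,
                 hu = hu, noise_sigma = noise_sigma,
                 motion_blur = motion_blur, fat_sheath = fat_sheath,
                 fat_thickness = fat_thickness, seed = as.integer(seed)),
            class = "coro_phantom_spec")
}

# raised-cosine bump in [0,1] over [s0, s0+L]
plaque_bump <- function(s, s0, L) {
  t <- (s - s0) / L
  b <- ifelse(t > 0 & t < 1, 0.5 * (1 - cos(2 * pi * t)), 0)
  b[is.na(b)] <- 0
  b
}

# vectorized radius profiles (s may contain NA)
phantom_profiles <- function(spec) {
  rl_base <- spec$lumen_radius
  wt_base <- spec$wall_thickness
  rl_fun <- if (is.function(rl_base)) rl_base else function(s) {
    rep_len(rl_base, length(s))
  }
  wt_fun <- if (is.function(wt_base)) wt_base else function(s) {
    rep_len(wt_base, length(s))
  }
  r_lumen <- function(s) {
    r <- rl_fun(s)
    for (p in spec$plaques)
      r <- r * (1 - p$lumen_narrowing_fraction *
                  plaque_bump(s, p$start_arc_length, p$length))
    r
  }
  r_outer <- function(s) {
    r <- rl_fun(s) + wt_fun(s)
    for (p in spec$plaques)
      r <- r + p$max_wall_thickening *
        plaque_bump(s, p$start_arc_length, p$length)
    r
  }
  list(r_lumen = r_lumen, r_outer = r_outer)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# outside the tube's end planes (vessel geometry is clipped there, so the
# rasterized volume matches the arc-length integral, no spherical caps)
cap_outside <- function(pts, cap) {
  if (is.null(cap)) return(rep(FALSE, nrow(pts)))
  u0 <- (pts[, 1] - cap$p0[1]) * cap$t0[1] +
    (pts[, 2] - cap$p0[2]) * cap$t0[2] +
    (pts[, 3] - cap$p0[3]) * cap$t0[3]
  u1 <- (pts[, 1] - cap$p1[1]) * cap$t1[1] +
    (pts[, 2] - cap$p1[2]) * cap$t1[2] +
    (pts[, 3] - cap$p1[3]) * cap$t1[3]
  u0 < 0 | u1 > 0
}

# classify (d, s) pairs into HU values; d = distance to centerline (mm)
phantom_hu_at <- function(d, s, prof, spec, pts = NULL, cap = NULL) {
  hu <- spec$hu
  out <- rep(hu$myocardium_hu, length(d))
  ok <- is.finite(d) & !is.na(s)
  if (!is.null(pts) && !is.null(cap)) ok <- ok & !cap_outside(pts, cap)
  rl <- rep(NA_real_, length(d)); ro <- rl
  rl[ok] <- prof$r_lumen(s[ok])
  ro[ok] <- prof$r_outer(s[ok])
  in_lumen <- ok & d <= rl
  in_wall <- ok & !in_lumen & d <= ro
  out[in_lumen] <- hu$lumen_hu
  out[in_wall] <- hu$wall_hu
  for (p in spec$plaques) {
    inwin <- in_wall & s > p$start_arc_length &
      s < p$start_arc_length + p$length
    if (!any(inwin)) next
    if (p$type == "soft") {
      out[inwin] <- hu$soft_plaque_hu
    } else if (p$type == "calcified") {
      out[inwin] <- hu$calcified_plaque_hu
    } else {
      mid <- (rl[inwin] + ro[inwin]) / 2
      out[inwin] <- ifelse(d[inwin] <= mid, hu$soft_plaque_hu,
                           hu$calcified_plaque_hu)
    }
  }
  if (isTRUE(spec$fat_sheath)) {
    # the sheath wraps the clipped tube ends too (perivascular fat runs on
    # along the artery), so nothing bright is exposed at the end discs
    ok2 <- is.finite(d) & !is.na(s)
    rl2 <- rep(NA_real_, length(d)); ro2 <- rl2
    rl2[ok2] <- prof$r_lumen(s[ok2]); ro2[ok2] <- prof$r_outer(s[ok2])
    in_fat <- ok2 & !in_lumen & !in_wall & d <= ro2 + spec$fat_thickness
    out[in_fat] <- hu$fat_hu
  }
  out
}

#' Generate a synthetic coronary CTA phantom with analytic ground truth
#'
#' Rasterizes the vessel defined by a [phantom_spec] onto the requested
#' lattice: voxels are classified by their distance to the centerline curve
#' against the lumen/outer radius profiles; boundary voxels are supersampled
#' 3x per axis and averaged (partial-volume model); optional motion blur and
#' seeded Gaussian noise are then applied. Ground-truth masks are noise-free
#' voxel-center rasterizations; analytic volumes come from arc-length
#' integration of pi r(s)^2.
#'
#' @param spec a [phantom_spec].
#' @param shape lattice dimensions (x, y, z).
#' @param spacing voxel size mm (scalar or length 3).
#' @param partial_volume supersample boundary voxels (default TRUE).
#' @return A \code{coro_phantom} list: \code{volume} (noisy),
#'   \code{clean} (pre-noise), \code{lumen_mask}, \code{vessel_mask},
#'   \code{centerline_points}, \code{arclen_field}, \code{dist_field},
#'   \code{analytic_lumen_volume}, \code{analytic_vessel_volume}, \code{spec}.
#' @export
make_phantom <- function(spec, shape = c(64, 64, 96), spacing = 0.4,
                         partial_volume = TRUE) {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  origin <- c(0, 0, 0)
  center <- (shape - 1) * spacing / 2
  prof <- phantom_profiles(spec)
  cp <- curve_points(spec$centerline_curve, center,
                     step = min(spacing) / 4)
  s_dense <- cp$arclen
  ro_max <- max(prof$r_outer(s_dense))
  rl_all <- prof$r_lumen(s_dense)
  if (any(rl_all <= 0)) stop("lumen radius must stay > 0 (narrowing < 1)")
  if (any(prof$r_outer(s_dense) < rl_all))
    stop("outer radius must be >= lumen radius everywhere")
  margin <- ro_max + (if (isTRUE(spec$fat_sheath)) spec$fat_thickness else 0)
  bounds_lo <- origin
  bounds_hi <- origin + (shape - 1) * spacing
  if (any(t(cp$points) < bounds_lo) || any(t(cp$points) > bounds_hi))
    stop("centerline curve exits the volume bounds")
  # full radial margin required away from the endpoints (a vessel may run
  # axially out of the field of view, as real arteries do)
  smax <- max(s_dense)
  mid <- s_dense > 2 * ro_max & s_dense < smax - 2 * ro_max
  if (any(t(cp$points[mid, , drop = FALSE]) - bounds_lo < margin) ||
      any(bounds_hi - t(cp$points[mid, , drop = FALSE]) < margin))
    stop("centerline curve does not fit inside the volume with margin >= outer radius")

  rmax <- margin + 4 * max(spacing)
  st <- .stamp_polyline_cpp(shape, spacing, origin, cp$points, s_dense,
                            rmax, NULL, NULL)
  D <- array(st$dist, dim = shape)
  A <- array(st$arclen, dim = shape)
  np <- nrow(cp$points)
  cap <- list(p0 = cp$points[1, ],
              t0 = cp$points[2, ] - cp$points[1, ],
              p1 = cp$points[np, ],
              t1 = cp$points[np, ] - cp$points[np - 1, ])
  cap$t0 <- cap$t0 / sqrt(sum(cap$t0^2))
  cap$t1 <- cap$t1 / sqrt(sum(cap$t1^2))
  ai <- arrayInd(seq_len(prod(shape)), shape)
  vox_pts <- cbind(origin[1] + (ai[, 1] - 1) * spacing[1],
                   origin[2] + (ai[, 2] - 1) * spacing[2],
                   origin[3] + (ai[, 3] - 1) * spacing[3])

  hu_center <- phantom_hu_at(as.numeric(D), as.numeric(A), prof, spec,
                             vox_pts, cap)
  clean <- array(hu_center, dim = shape)

  if (isTRUE(partial_volume)) {
    # supersample voxels near any class boundary: 3 samples per axis,
    # distances/arc lengths interpolated from the stamped fields
    rl <- prof$r_lumen(as.numeric(A)); ro <- prof$r_outer(as.numeric(A))
    bw <- 1.2 * max(spacing)
    near <- is.finite(D) & !is.na(A) &
      (abs(D - rl) < bw | abs(D - ro) < bw |
         (isTRUE(spec$fat_sheath) & abs(D - (ro + spec$fat_thickness)) < bw))
    idx <- which(near)
    if (length(idx)) {
      ijk <- arrayInd(idx, shape) - 1L
      offs <- as.matrix(expand.grid(o1 = c(-1, 0, 1) / 3,
                                    o2 = c(-1, 0, 1) / 3,
                                    o3 = c(-1, 0, 1) / 3))
      acc <- numeric(length(idx))
      base_mm <- sweep(ijk, 2, spacing, `*`)
      base_mm <- sweep(base_mm, 2, origin, `+`)
      for (k in seq_len(nrow(offs))) {
        pts <- sweep(base_mm, 2, offs[k, ] * spacing, `+`)
        dv <- .sample_volume_cpp(as.numeric(D), shape, spacing, origin,
                                 pts, 0L, Inf)$values
        av <- .sample_volume_cpp(ifelse(is.na(as.numeric(A)), -1e9,
                                        as.numeric(A)),
                                 shape, spacing, origin, pts, 0L,
                                 -1e9)$values
        av[av < -1e8] <- NA
        acc <- acc + phantom_hu_at(dv, av, prof, spec, pts, cap)
      }
      clean[idx] <- acc / nrow(offs)
    }
  }

  # noise-free voxel-center ground-truth masks
  rlc <- prof$r_lumen(as.numeric(A))
  roc <- prof$r_outer(as.numeric(A))
  okc <- is.finite(as.numeric(D)) & !is.na(as.numeric(A)) &
    !cap_outside(vox_pts, cap)
  lumen_mask <- array(okc & as.numeric(D) <= rlc, dim = shape)
  vessel_mask <- array(okc & as.numeric(D) <= roc, dim = shape)

  # motion blur: blend a Gaussian-blurred copy over an arc-length window
  if (!is.null(spec$motion_blur)) {
    mb <- spec$motion_blur
    blurred <- gauss_filter3(clean, spacing, mb$sigma)
    tr <- if (is.null(mb$transition)) 1.0 else mb$transition
    w <- rep(0, length(A))
    sA <- as.numeric(A)
    inw <- !is.na(sA)
    ramp <- function(x) pmin(1, pmax(0, x))
    w[inw] <- ramp((sA[inw] - mb$window[1]) / tr) *
      ramp((mb$window[2] - sA[inw]) / tr)
    clean <- array((1 - w) * as.numeric(clean) + w * as.numeric(blurred),
                   dim = shape)
  }

  vol_data <- if (spec$noise_sigma > 0) {
    noise <- with_local_seed(spec$seed,
                             stats::rnorm(prod(shape), 0, spec$noise_sigma))
    array(as.numeric(clean) + noise, dim = shape)
  } else clean

  s_an <- s_dense
  alv <- sum(diff(s_an) * (pi * prof$r_lumen(s_an)^2)[-1] / 2 +
               diff(s_an) * (pi * prof$r_lumen(s_an)^2)[-length(s_an)] / 2)
  avv <- sum(diff(s_an) * (pi * prof$r_outer(s_an)^2)[-1] / 2 +
               diff(s_an) * (pi * prof$r_outer(s_an)^2)[-length(s_an)] / 2)

  keep <- seq(1, length(s_dense), by = max(1L, as.integer(round(
    0.25 / (min(spacing) / 4)))))
  structure(list(
    volume = coro_volume(vol_data, spacing, origin),
    clean = coro_volume(clean, spacing, origin),
    lumen_mask = coro_mask(lumen_mask, spacing = spacing, origin = origin),
    vessel_mask = coro_mask(vessel_mask, spacing = spacing, origin = origin),
    centerline_points = cp$points[keep, , drop = FALSE],
    centerline_arclen = s_dense[keep],
    arclen_field = A, dist_field = D,
    analytic_lumen_volume = alv, analytic_vessel_volume = avv,
    spec = spec), class = "coro_phantom")
}

# re-apply seeded noise to a modified clean volume
phantom_renoise <- function(truth) {
  spec <- truth$spec
  shape <- dim(truth$clean$data)
  if (spec$noise_sigma > 0) {
    noise <- with_local_seed(spec$seed,
                             stats::rnorm(prod(shape), 0, spec$noise_sigma))
    truth$volume <- coro_volume(array(as.numeric(truth$clean$data) + noise,
                                      dim = shape),
                                truth$clean$spacing, truth$clean$origin)
  } else truth$volume <- truth$clean
  truth
}

#' Add a bright sheet confounder near (but disjoint from) the vessel
#'
#' Inserts a thin bright slab whose nearest face lies \code{offset} mm from
#' the vessel surface, emulating vessel-adjacent sheet-like structures that
#' the vesselness filter can falsely enhance. Ground-truth masks are
#' unchanged; overlap with the vessel is a geometry error.
#'
#' @param truth a \code{coro_phantom}.
#' @param offset mm gap between vessel surface and sheet.
#' @param hu sheet intensity in HU (exact, before noise).
#' @param thickness sheet thickness mm.
#' @param width sheet extent along y in mm (a ribbon, not an infinite plane).
#' @return The modified \code{coro_phantom}; the sheet voxels are recorded in
#'   \code{attr(, "sheet_mask")}.
#' @export
confounder_bright_sheet <- function(truth, offset = 3, hu = 400,
                                    thickness = 0.6, width = 6) {
  vol <- truth$clean
  shape <- dim(vol$data)
  sp <- vol$spacing
  xs <- vol$origin[1] + (seq_len(shape[1]) - 1) * sp[1]
  ys <- vol$origin[2] + (seq_len(shape[2]) - 1) * sp[2]
  vx <- which(truth$vessel_mask$data, arr.ind = TRUE)
  xmax_v <- max(xs[vx[, 1]])
  x0 <- xmax_v + offset + thickness / 2
  cy <- mean(range(ys[vx[, 2]]))
  in_x <- abs(xs - x0) <= thickness / 2
  in_y <- abs(ys - cy) <= width / 2
  sheet <- array(FALSE, dim = shape)
  sheet[in_x, in_y, ] <- TRUE
  if (any(sheet & truth$vessel_mask$data))
    stop("bright sheet would intersect the vessel; increase offset")
  vol$data[sheet] <- hu
  truth$clean <- vol
  truth <- phantom_renoise(truth)
  attr(truth, "sheet_mask") <- coro_mask(sheet, spacing = sp,
                                         origin = vol$origin)
  truth
}

#' Add an adjacent-vein confounder
#'
#' Adds a parallel tube at wall-like HU whose surface lies \code{gap} mm from
#' the artery surface (gap 0 = touching), emulating coronary veins in close
#' proximity that can merge with the outer wall. Ground-truth masks are
#' unchanged.
#'
#' @param truth a \code{coro_phantom}.
#' @param gap mm surface-to-surface distance (>= 0).
#' @param radius vein radius mm.
#' @return The modified \code{coro_phantom}; vein voxels recorded in
#'   \code{attr(, "vein_mask")}.
#' @export
confounder_adjacent_vein <- function(truth, gap = 0, radius = 1.25) {
  if (gap < 0) stop("gap must be >= 0")
  vol <- truth$clean
  shape <- dim(vol$data)
  sp <- vol$spacing
  prof <- phantom_profiles(truth$spec)
  ro_max <- max(prof$r_outer(truth$centerline_arclen))
  shift <- ro_max + gap + radius
  pts <- truth$centerline_points
  pts[, 1] <- pts[, 1] + shift
  st <- .stamp_polyline_cpp(shape, sp, vol$origin, pts,
                            truth$centerline_arclen, radius + 2 * max(sp),
                            NULL, NULL)
  vein <- array(st$dist <= radius, dim = shape)
  vol$data[vein & !truth$vessel_mask$data] <- truth$spec$hu$wall_hu
  truth$clean <- vol
  truth <- phantom_renoise(truth)
  attr(truth, "vein_mask") <- coro_mask(vein, spacing = sp,
                                        origin = vol$origin)
  truth
}

#' Mask of phantom voxels within an arc-length window
#'
#' Selects voxels whose nearest-centerline arc length falls in
#' \code{[s0, s1]} -- used to restrict metrics to e.g. the segment distal to
#' an artifact, or to crop per-plaque masks.
#'
#' @param truth a \code{coro_phantom}.
#' @param s0,s1 arc-length bounds in mm.
#' @return A [coro_mask].
#' @export
arc_window_mask <- function(truth, s0, s1) {
  A <- truth$arclen_field
  m <- !is.na(A) & A >= s0 & A <= s1
  coro_mask(array(m, dim = dim(A)), spacing = truth$volume$spacing,
            origin = truth$volume$origin)
}
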