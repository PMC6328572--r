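#' Curved multiplanar reformation: straighten a volume along a centerline
#'
#' Resamples the volume on planes orthogonal to the centerline tangent at
#' every arc-length point: slice i of the output is sampled on the plane
#' spanned by the (parallel-transport-corrected) normal and binormal at
#' point i, on an mm grid centered on the centerline. HU volumes use linear
#' interpolation. Masks stay binary but are resampled through their signed
#' distance field (linear interpolation, thresholded at zero), which
#' preserves the sub-voxel boundary position instead of the raw voxel
#' staircase; set \code{interpolation = "nearest"} to sample mask voxels
#' directly. Out-of-bounds samples get \code{fill} and are counted per
#' slice.
#'
#' @param x a [coro_volume] or [coro_mask].
#' @param centerline a \code{coro_centerline} with frames.
#' @param half_width in-plane half extent mm (default 10).
#' @param in_plane_step in-plane sample step mm (default 0.2).
#' @param interpolation "linear" or "nearest" (masks force nearest).
#' @param fill out-of-bounds fill value.
#' @return A \code{coro_straight}: \code{data} (arc x u x v),
#'   \code{arc_length}, \code{in_plane_step}, \code{half_width},
#'   \code{centerline}, \code{interpolation}, \code{oob_per_slice},
#'   \code{is_mask}.
#' @export
straighten <- function(x, centerline, half_width = 10, in_plane_step = 0.2,
                       interpolation = c("linear", "nearest"), fill = NA) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(x, "coro_mask")
  if (is.null(centerline$normal)) stop("centerline frames are not filled")
  mask_sdf <- is_mask && interpolation == "linear"
  dat <- if (mask_sdf) {
    array(.signed_distance_cpp(as.logical(x$data), dim(x$data), x$spacing),
          dim = dim(x$data))
  } else if (is_mask) {
    array(as.numeric(x$data), dim = dim(x$data))
  } else x$data
  uu <- seq(-half_width, half_width, by = in_plane_step)
  nu <- length(uu)
  npts <- nrow(centerline$points)
  out <- array(NA_real_, dim = c(npts, nu, nu))
  oob <- integer(npts)
  grid_uv <- as.matrix(expand.grid(u = uu, v = uu))
  fillv <- if (mask_sdf) 1e6 else if (is_mask) 0 else
    ifelse(is.na(fill), NA_real_, fill)
  mode <- if (interpolation == "nearest") 1L else 0L
  for (i in seq_len(npts)) {
    p <- centerline$points[i, ]
    Nv <- centerline$normal[i, ]; Bv <- centerline$binormal[i, ]
    pts <- cbind(p[1] + grid_uv[, 1] * Nv[1] + grid_uv[, 2] * Bv[1],
                 p[2] + grid_uv[, 1] * Nv[2] + grid_uv[, 2] * Bv[2],
                 p[3] + grid_uv[, 1] * Nv[3] + grid_uv[, 2] * Bv[3])
    sm <- .sample_volume_cpp(as.numeric(dat), dim(dat), x$spacing, x$origin,
                             pts, mode, ifelse(is.na(fillv), NA_real_,
                                               fillv))
    out[i, , ] <- if (mask_sdf) matrix(as.numeric(sm$values <= 0), nu, nu)
      else matrix(sm$values, nu, nu)
    oob[i] <- sum(sm$oob)
  }
  structure(list(data = out, arc_length = centerline$arc_length,
                 in_plane_step = in_plane_step, half_width = half_width,
                 centerline = centerline, interpolation = interpolation,
                 oob_per_slice = oob, is_mask = is_mask),
            class = "coro_straight")
}

# bilinear / nearest sample of one straightened slice at in-plane mm coords
sample_slice <- function(slice, half_width, step, u, v, nearest = FALSE) {
  nu <- nrow(slice)
  iu <- (u + half_width) / step
  iv <- (v + half_width) / step
  if (nearest) {
    iu <- round(iu); iv <- round(iv)
    ok <- iu >= 0 & iu <= nu - 1 & iv >= 0 & iv <= nu - 1
    val <- rep(NA_real_, length(u))
    val[ok] <- slice[cbind(iu[ok] + 1, iv[ok] + 1)]
    return(val)
  }
  i0 <- pmin(pmax(floor(iu), 0), nu - 2)
  j0 <- pmin(pmax(floor(iv), 0), nu - 2)
  tx <- iu - i0; ty <- iv - j0
  ok <- iu >= 0 & iu <= nu - 1 & iv >= 0 & iv <= nu - 1
  v00 <- slice[cbind(i0 + 1, j0 + 1)]
  v10 <- slice[cbind(i0 + 2, j0 + 1)]
  v01 <- slice[cbind(i0 + 1, j0 + 2)]
  v11 <- slice[cbind(i0 + 2, j0 + 2)]
  val <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  val[!ok] <- NA_real_
  val
}

#' Radial longitudinal sections through a straightened vessel
#'
#' Section k is the longitudinal plane through the centerline column at
#' angle k * (180 / n_sections) degrees; 5 sections give the conventional
#' 36 degree angular gap, 20 sections give 9 degrees. Each section is an
#' arc-length x diameter image.
#'
#' @param straight a \code{coro_straight}.
#' @param n_sections number of radial sections (>= 1).
#' @return list of matrices (one per section) with attributes
#'   \code{angles_deg} and \code{angular_gap_deg}.
#' @export
radial_sections <- function(straight, n_sections = 5) {
  if (n_sections < 1) stop("n_sections must be >= 1")
  hw <- straight$half_width; st <- straight$in_plane_step
  tt <- seq(-hw, hw, by = st)
  nslice <- dim(straight$data)[1]
  angles <- (seq_len(n_sections) - 1) * 180 / n_sections
  secs <- lapply(angles, function(adeg) {
    a <- adeg * pi / 180
    u <- tt * cos(a); v <- tt * sin(a)
    m <- matrix(NA_real_, nslice, length(tt))
    for (i in seq_len(nslice))
      m[i, ] <- sample_slice(straight$data[i, , ], hw, st, u, v,
                             nearest = straight$is_mask)
    m
  })
  attr(secs, "angles_deg") <- angles
  attr(secs, "angular_gap_deg") <- 180 / n_sections
  secs
}

#' Wall thickness profile along a straightened vessel
#'
#' Per cross-section, the mean over \code{n_rays} rays from the centerline
#' of (vessel boundary radius - lumen boundary radius); boundary radii are
#' located at the first foreground-to-background transition along each ray
#' (midpoint convention). Areas are mask pixel counts times pixel area.
#' Slices whose center is not inside the lumen are flagged missing.
#'
#' @param straight_lumen,straight_vessel straightened mask volumes on the
#'   same grid (from [straighten]).
#' @param n_rays number of rays (default 360).
#' @return A data.frame: \code{arc_length}, \code{mean_thickness},
#'   \code{lumen_area}, \code{vessel_area}, \code{missing}.
#' @export
wall_thickness_profile <- function(straight_lumen, straight_vessel,
                                   n_rays = 360) {
  if (!identical(dim(straight_lumen$data), dim(straight_vessel$data)))
    stop("straightened lumen and vessel are not on the same grid")
  hw <- straight_lumen$half_width
  st <- straight_lumen$in_plane_step
  nslice <- dim(straight_lumen$data)[1]
  rstep <- st / 2
  rr <- seq(0, hw, by = rstep)
  th <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  pxa <- st^2
  res <- data.frame(arc_length = straight_lumen$arc_length,
                    mean_thickness = NA_real_, lumen_area = NA_real_,
                    vessel_area = NA_real_, missing = FALSE)
  boundary_r <- function(slice, u, v) {
    val <- sample_slice(slice, hw, st, u, v, nearest = TRUE)
    val[is.na(val)] <- 0
    off <- which(val < 0.5)
    if (length(off) == 0) return(rr[length(rr)])
    j <- off[1]
    if (j == 1) return(0)
    (rr[j - 1] + rr[j]) / 2
  }
  for (i in seq_len(nslice)) {
    sl <- straight_lumen$data[i, , ]
    sv <- straight_vessel$data[i, , ]
    res$lumen_area[i] <- sum(sl > 0.5, na.rm = TRUE) * pxa
    res$vessel_area[i] <- sum(sv > 0.5, na.rm = TRUE) * pxa
    ctr <- sample_slice(sl, hw, st, 0, 0, nearest = TRUE)
    if (is.na(ctr) || ctr < 0.5) {
      res$missing[i] <- TRUE
      next
    }
    thk <- vapply(th, function(a) {
      u <- rr * cos(a); v <- rr * sin(a)
      rl <- boundary_r(sl, u, v)
      rv <- boundary_r(sv, u, v)
      max(rv - rl, 0)
    }, 0.0)
    res$mean_thickness[i] <- mean(thk)
  }
  class(res) <- c("coro_thickness", "data.frame")
  res
}
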