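#' Extract the zero-level (or iso-level) surface mesh
#'
#' Triangulates the implicit surface of a binary mask or a signed-distance /
#' scalar lattice in physical mm coordinates, with consistent outward
#' orientation (normals toward increasing values; masks are converted to a
#' signed distance, negative inside). Masks are lightly smoothed in the
#' implicit domain (Gaussian, default 0.6 x min spacing) to suppress
#' voxelization roughness; pass \code{smooth_sigma = 0} to disable.
#'
#' @param x a [coro_mask], or a [coro_volume] holding a scalar lattice.
#' @param level iso level (0 for signed distance).
#' @param smooth_sigma mm; NA chooses 0.6 x min spacing for masks, 0 for
#'   scalar input.
#' @param provenance "lumen" or "vessel" label carried on the mesh.
#' @return A \code{coro_mesh}: \code{vertices} (n x 3 mm), \code{faces}
#'   (m x 3, 1-based), \code{provenance}; the source mask is kept in
#'   \code{attr(, "source_mask")} for centerline extraction.
#' @export
extract_mesh <- function(x, level = 0, smooth_sigma = NA,
                         provenance = "lumen") {
  if (inherits(x, "coro_mask")) {
    src_mask <- x
    phi <- array(.signed_distance_cpp(as.logical(x$data), dim(x$data),
                                      x$spacing), dim = dim(x$data))
    if (is.na(smooth_sigma)) smooth_sigma <- 0.6 * min(x$spacing)
    if (smooth_sigma > 0) phi <- gauss_filter3(phi, x$spacing, smooth_sigma)
    grid <- x
    level <- 0
  } else if (inherits(x, "coro_volume")) {
    phi <- x$data
    src_mask <- coro_mask(phi <= level, spacing = x$spacing,
                          origin = x$origin)
    if (!is.na(smooth_sigma) && smooth_sigma > 0)
      phi <- gauss_filter3(phi, x$spacing, smooth_sigma)
    grid <- x
  } else stop("x must be a coro_mask or coro_volume")
  if (level < min(phi) || level > max(phi))
    stop("iso level outside the data range; no surface to extract")
  mt <- .marching_tetrahedra_cpp(as.numeric(phi), dim(phi), grid$spacing,
                                 grid$origin, level)
  structure(list(vertices = mt$vertices, faces = mt$faces,
                 provenance = provenance),
            class = "coro_mesh", source_mask = src_mask)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a \code{coro_mesh}.
#' @return scalar mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 2], ] - V[F[, 1], ]
  b <- V[F[, 3], ] - V[F[, 1], ]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a closed mesh via the divergence theorem (mm^3)
#' @param mesh a \code{coro_mesh}.
#' @return scalar mm^3 (positive for outward-oriented closed surfaces).
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  v1 <- V[F[, 1], ]; v2 <- V[F[, 2], ]; v3 <- V[F[, 3], ]
  # signed tetrahedron volumes against the origin; orientation is outward,
  # with vertex order v1, v2, v3 counter-clockwise seen from outside
  det <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
    v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(sum(det)) / 6
}

# Euler characteristic V - E + F (2 for a closed genus-0 surface)
#' @rdname mesh_area
#' @export
mesh_euler <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  nrow(mesh$vertices) - nrow(e) + nrow(F)
}

#' Export a mesh as ASCII PLY or STL
#' @param mesh a \code{coro_mesh}.
#' @param path output path; format from extension (.ply / .stl).
#' @return invisibly, \code{path}.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; F <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"),
               con)
    writeLines(sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$provenance), con)
    for (i in seq_len(nrow(F))) {
      tri <- V[F[i, ], , drop = FALSE]
      n <- c((tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) -
               (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
             (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) -
               (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
             (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
               (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
      nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
      writeLines(c(sprintf("  facet normal %.6f %.6f %.6f", n[1], n[2], n[3]),
                   "    outer loop",
                   sprintf("      vertex %.6f %.6f %.6f",
                           tri[, 1], tri[, 2], tri[, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid", con)
  } else stop("unsupported mesh format: use .ply or .stl")
  invisible(path)
}

#' Extract the medial-axis centerline between two seed points
#'
#' The medial path maximizes distance to the surface: the interior Euclidean
#' distance transform supplies a per-voxel inscribed radius, a shortest path
#' from source to target is computed on the interior lattice graph with edge
#' costs inversely weighted by that radius (so the path rides the medial
#' ridge), and the raw voxel path is then smoothed (Gaussian along arc
#' length, deviation-capped at 0.3 mm) and resampled at a uniform step.
#'
#' @param x a \code{coro_mesh} from [extract_mesh] (its source mask is used)
#'   or a lumen [coro_mask].
#' @param source,target [seed_point]s (or mm coordinates) inside the lumen.
#' @param step resample step mm (default 0.25).
#' @param smooth_mm Gaussian smoothing length scale along the path.
#' @return A \code{coro_centerline}: \code{points}, \code{arc_length},
#'   \code{tangent}, \code{normal}, \code{binormal},
#'   \code{max_inscribed_radius}, \code{curvature}.
#' @export
extract_centerline <- function(x, source, target, step = 0.25,
                               smooth_mm = 2) {
  mask <- if (inherits(x, "coro_mesh")) attr(x, "source_mask") else x
  if (!inherits(mask, "coro_mask")) stop("no source mask available")
  dims <- dim(mask$data)
  sp <- mask$spacing
  r_in <- sqrt(array(.edt_sq_cpp(as.logical(!mask$data), dims, sp),
                     dim = dims))
  r_in <- pmax(r_in - 0.5 * min(sp), 0.05 * min(sp))  # center on surface
  # nearest in-lumen voxel to the clicked seed (within 1.5 mm); keeping the
  # endpoint where the user put it preserves the path's arc length
  snap <- function(seedp) {
    pos <- if (inherits(seedp, "coro_seed")) seedp$position else
      as.numeric(seedp)
    m <- physical_to_index(mask, pos)
    if (!m$in_bounds) stop("centerline seed outside volume bounds")
    ijk <- as.integer(round(m$index))
    rad <- ceiling(1.5 / sp)
    lo <- pmax(ijk - rad, 0L); hi <- pmin(ijk + rad, dims - 1L)
    msub <- mask$data[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                      (lo[3] + 1):(hi[3] + 1), drop = FALSE]
    if (!any(msub)) stop("centerline seed is not inside the lumen")
    cand <- arrayInd(which(msub), dim(msub)) - 1L
    cmm <- sweep(sweep(cand, 2, lo, `+`), 2, sp, `*`)
    cmm <- sweep(cmm, 2, mask$origin, `+`)
    d2 <- rowSums(sweep(cmm, 2, pos, `-`)^2)
    lo + as.integer(cand[which.min(d2), ])
  }
  s_ijk <- snap(source); t_ijk <- snap(target)
  src <- array(FALSE, dim = dims)
  src[s_ijk[1] + 1, s_ijk[2] + 1, s_ijk[3] + 1] <- TRUE
  cost <- 1 / (r_in + 0.25)^3
  gd <- .geodesic_dist_cpp(as.logical(src), as.logical(mask$data), dims, sp,
                           as.numeric(cost), -1, 26L, FALSE)
  tlin <- linear_index(dims, t_ijk)
  if (!is.finite(gd$dist[tlin + 1]))
    stop(paste("no interior path from source to target: the lumen interior",
               "is disconnected (broken/discontinuous segmentation)"))
  # back-trace predecessors
  path <- integer(0)
  cur <- tlin
  while (cur >= 0) {
    path <- c(path, cur)
    cur <- gd$pred[cur + 1]
  }
  path <- rev(path)
  ijk <- arrayInd(path + 1, dims) - 1L
  pts <- sweep(sweep(ijk, 2, sp, `*`), 2, mask$origin, `+`)

  # arc-length parameter of the raw voxel path
  seglen <- sqrt(rowSums(diff(pts)^2))
  al <- c(0, cumsum(seglen))
  # Gaussian smoothing along arc length, capped at 0.3 mm max deviation
  sm <- smooth_mm
  repeat {
    smoothed <- apply(pts, 2, function(cc) {
      vapply(seq_along(al), function(i) {
        w <- exp(-(al - al[i])^2 / (2 * sm^2))
        sum(w * cc) / sum(w)
      }, 0.0)
    })
    dev <- sqrt(rowSums((smoothed - pts)^2))
    if (max(dev) <= 0.3 || sm <= 0.25) break
    sm <- sm / 1.5
  }
  # resample at uniform arc-length step via cubic splines
  al2 <- c(0, cumsum(sqrt(rowSums(diff(smoothed)^2))))
  keep <- c(TRUE, diff(al2) > 1e-9)
  al2 <- al2[keep]; smoothed <- smoothed[keep, , drop = FALSE]
  su <- seq(0, max(al2), by = step)
  if (length(su) < 3) su <- seq(0, max(al2), length.out = 3)
  rs <- vapply(1:3, function(d)
    stats::spline(al2, smoothed[, d], xout = su)$y,
    numeric(length(su)))
  arc <- c(0, cumsum(sqrt(rowSums(diff(rs)^2))))
  rad <- .sample_volume_cpp(as.numeric(r_in), dims, sp, mask$origin,
                            rs, 0L, 0)$values
  cl <- structure(list(points = rs, arc_length = arc,
                       tangent = NULL, normal = NULL, binormal = NULL,
                       curvature = NULL,
                       max_inscribed_radius = rad),
                  class = "coro_centerline")
  compute_frames(cl)
}

#' Attach orthonormal frames to a centerline
#'
#' Tangents come from arc-length derivatives. Where curvature exceeds the
#' threshold the normal/binormal follow the Frenet-Serret construction
#' (normal along dT/ds); in degenerate (near-straight) stretches, where the
#' Frenet normal is undefined, frames are continued by rotation-minimizing
#' parallel transport. A continuity correction flips the Frenet normal when
#' needed so consecutive frames never jump antipodally.
#'
#' @param centerline a \code{coro_centerline} with >= 3 points.
#' @param curvature_threshold mm^-1 below which parallel transport is used.
#' @return The centerline with \code{tangent}, \code{normal},
#'   \code{binormal}, \code{curvature} filled.
#' @export
compute_frames <- function(centerline, curvature_threshold = 1e-4) {
  P <- centerline$points
  n <- nrow(P)
  if (n < 3) stop("at least 3 centerline points are required")
  if (any(rowSums(diff(P)^2) < 1e-18))
    stop("duplicate consecutive centerline points")
  al <- centerline$arc_length
  d1 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    d1[i, ] <- (P[b, ] - P[a, ]) / (al[b] - al[a])
  }
  Tm <- d1 / sqrt(rowSums(d1^2))
  dT <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- max(1, i - 1); b <- min(n, i + 1)
    dT[i, ] <- (Tm[b, ] - Tm[a, ]) / (al[b] - al[a])
  }
  kap <- sqrt(rowSums(dT^2))

  Nm <- matrix(0, n, 3); Bm <- matrix(0, n, 3)
  # initial normal: least-aligned axis, projected orthogonal to T
  e <- diag(3)[, which.min(abs(Tm[1, ]))]
  n0 <- e - sum(e * Tm[1, ]) * Tm[1, ]
  n_prev <- n0 / sqrt(sum(n0^2))
  for (i in seq_len(n)) {
    nt <- n_prev - sum(n_prev * Tm[i, ]) * Tm[i, ]
    nt <- nt / sqrt(sum(nt^2))
    if (kap[i] >= curvature_threshold) {
      nf <- dT[i, ] - sum(dT[i, ] * Tm[i, ]) * Tm[i, ]
      nn <- sqrt(sum(nf^2))
      if (nn > 0) {
        nf <- nf / nn
        if (sum(nf * nt) < 0) nf <- -nf  # continuity correction
        nt <- nf
      }
    }
    Nm[i, ] <- nt
    Bm[i, ] <- c(Tm[i, 2] * nt[3] - Tm[i, 3] * nt[2],
                 Tm[i, 3] * nt[1] - Tm[i, 1] * nt[3],
                 Tm[i, 1] * nt[2] - Tm[i, 2] * nt[1])
    n_prev <- nt
  }
  centerline$tangent <- Tm
  centerline$normal <- Nm
  centerline$binormal <- Bm
  centerline$curvature <- kap
  centerline
}

#' Export a centerline as tab-separated text
#'
#' Columns: x, y, z, arclen, Tx..Tz, Nx..Nz, Bx..Bz, radius.
#' @param centerline a \code{coro_centerline}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_centerline <- function(centerline, path) {
  df <- data.frame(centerline$points, centerline$arc_length,
                   centerline$tangent, centerline$normal,
                   centerline$binormal, centerline$max_inscribed_radius)
  names(df) <- c("x", "y", "z", "arclen", "Tx", "Ty", "Tz",
                 "Nx", "Ny", "Nz", "Bx", "By", "Bz", "radius")
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
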