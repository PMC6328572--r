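#' @useDynLib coroseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a 3D scalar volume
#'
#' The common currency of all stages: a 3D lattice (Hounsfield units for CTA
#' input, unitless for derived images) with per-axis voxel size and the
#' physical position of voxel (0,0,0). Voxel indices are 0-based and refer to
#' voxel centers; the physical coordinate of index \code{i} is
#' \code{origin + i * spacing}. Array dimensions are (x, y, z).
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return A \code{coro_volume} object.
#' @export
coro_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 2L))
    stop("every volume axis must have at least 2 voxels")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "coro_volume")
}

#' Construct a binary mask on a volume's lattice
#'
#' @param data logical 3D array (or coercible).
#' @param grid a \code{coro_volume} or \code{coro_mask} supplying
#'   spacing/origin, or NULL with explicit spacing/origin.
#' @param spacing,origin grid metadata used when \code{grid} is NULL.
#' @return A \code{coro_mask} object.
#' @export
coro_mask <- function(data, grid = NULL, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0)) {
  if (!is.null(grid)) {
    spacing <- grid$spacing
    origin <- grid$origin
    if (!is.null(grid$data) && !identical(dim(as.array(data)), dim(grid$data)))
      stop("mask shape must match its parent volume")
  }
  data <- array(as.logical(data), dim = dim(as.array(data)))
  if (any(is.na(data))) stop("mask may not contain NA")
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "coro_mask")
}

#' @export
print.coro_volume <- function(x, ...) {
  cat(sprintf("coro_volume %s, spacing %s mm, origin %s mm, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.coro_mask <- function(x, ...) {
  cat(sprintf("coro_mask %s, spacing %s mm, %d foreground voxels\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

#' A labelled seed point in physical coordinates
#'
#' @param position numeric length-3 position in mm.
#' @param label one of "RCA_ostium", "LM_ostium", "generic".
#' @return A \code{coro_seed} object.
#' @export
seed_point <- function(position, label = c("generic", "RCA_ostium",
                                           "LM_ostium")) {
  label <- match.arg(label)
  position <- as.numeric(position)
  if (length(position) != 3L || any(!is.finite(position)))
    stop("seed position must be 3 finite mm coordinates")
  structure(list(position = position, label = label), class = "coro_seed")
}

#' Map a physical point (mm) to a continuous 0-based lattice index
#'
#' Inverse of the index-to-physical map. Out-of-bounds points are returned
#' with \code{in_bounds = FALSE}, never clamped silently.
#'
#' @param volume a \code{coro_volume} or \code{coro_mask}.
#' @param point numeric length-3 mm coordinate.
#' @return list with \code{index} (continuous, 0-based) and \code{in_bounds}.
#' @export
physical_to_index <- function(volume, point) {
  idx <- (as.numeric(point) - volume$origin) / volume$spacing
  dims <- dim(volume$data)
  list(index = idx,
       in_bounds = all(idx >= 0 & idx <= dims - 1))
}

#' Map a 0-based lattice index to physical mm coordinates
#' @param volume a \code{coro_volume} or \code{coro_mask}.
#' @param index numeric length-3 (may be continuous).
#' @return numeric length-3 mm coordinate.
#' @export
index_to_physical <- function(volume, index) {
  volume$origin + as.numeric(index) * volume$spacing
}

#' Volume of one voxel in mm^3
#' @param x a \code{coro_volume} or \code{coro_mask}.
#' @return scalar mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

# grid identity check used throughout
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("inputs are not on the same lattice/grid")
  invisible(TRUE)
}

# nearest voxel (0-based integer index) for a physical point; errors if out
seed_voxel <- function(volume, seed) {
  pos <- if (inherits(seed, "coro_seed")) seed$position else as.numeric(seed)
  m <- physical_to_index(volume, pos)
  if (!m$in_bounds)
    stop(sprintf("seed (%s) lies outside the volume's physical bounds",
                 paste(signif(pos, 4), collapse = ", ")))
  as.integer(round(m$index))
}

# 0-based linear index from 0-based (x,y,z)
linear_index <- function(dims, ijk) {
  ijk[1] + dims[1] * (ijk[2] + dims[2] * ijk[3])
}
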