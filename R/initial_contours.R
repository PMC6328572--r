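#' Region-growing parameters
#' @param lower_threshold,upper_threshold inclusive value window (HU for the
#'   CTA image, vesselness units for the filtered image).
#' @param connectivity 6 or 26 neighbourhood.
#' @return A \code{coro_rg_params} list.
#' @export
region_grow_params <- function(lower_threshold, upper_threshold,
                               connectivity = 26) {
  if (lower_threshold > upper_threshold)
    stop("lower_threshold must be <= upper_threshold")
  if (!connectivity %in% c(6, 26))
    stop("connectivity must be 6 or 26")
  structure(list(lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold,
                 connectivity = as.integer(connectivity)),
            class = "coro_rg_params")
}

#' Parameters for the outer-wall initial contour
#'
#' The lumen is extended by a restricted (geodesic) morphological dilation of
#' \code{dilation_distance} mm (default 5.5 mm, sized to enclose the thickest
#' plaques) through the domain of voxels with HU at or above
#' \code{fat_hu_threshold}; perivascular fat (negative HU) blocks propagation.
#'
#' @param dilation_distance mm (> 0), default 5.5.
#' @param fat_hu_threshold HU below which voxels are treated as fat (default 0).
#' @param surface_offset add half a voxel to the distance threshold to
#'   account for the gap between a boundary voxel's center (where lattice
#'   distances are measured) and the lumen region's surface (default TRUE).
#' @return A \code{coro_outer_params} list.
#' @export
outer_init_params <- function(dilation_distance = 5.5, fat_hu_threshold = 0,
                              surface_offset = TRUE) {
  if (dilation_distance <= 0) stop("dilation_distance must be > 0")
  structure(list(dilation_distance = dilation_distance,
                 fat_hu_threshold = fat_hu_threshold,
                 surface_offset = isTRUE(surface_offset)),
            class = "coro_outer_params")
}

#' Seeded region growing
#'
#' Maximal connected component(s) of voxels whose value lies in the window,
#' reachable from the seeds under the stated connectivity.
#'
#' @param image a [coro_volume] (or vesselness image).
#' @param seeds list of [seed_point]s or a single seed, mm coordinates.
#' @param params a [region_grow_params].
#' @return A [coro_mask].
#' @export
region_grow <- function(image, seeds, params) {
  stopifnot(inherits(image, "coro_volume"))
  if (inherits(seeds, "coro_seed") || is.numeric(seeds)) seeds <- list(seeds)
  dims <- dim(image$data)
  lin <- integer(0)
  for (s in seeds) {
    ijk <- seed_voxel(image, s)
    val <- image$data[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1]
    if (val < params$lower_threshold || val > params$upper_threshold) {
      pos <- if (inherits(s, "coro_seed")) s$position else s
      stop(sprintf(
        "seed at (%s) rejected: value %.3g outside window [%g, %g]",
        paste(signif(pos, 4), collapse = ", "), val,
        params$lower_threshold, params$upper_threshold))
    }
    lin <- c(lin, linear_index(dims, ijk))
  }
  res <- .region_grow_cpp(as.numeric(image$data), dims, as.integer(lin),
                          params$lower_threshold, params$upper_threshold,
                          params$connectivity)
  coro_mask(array(res, dim = dims), spacing = image$spacing,
            origin = image$origin)
}

#' Robust lumen initial contour (S1)
#'
#' Region growing is applied independently to the HU image and to the
#' vesselness image, and the two binary results are intersected. The HU
#' growth keeps only blood-pool-connected voxels (excluding vesselness
#' artifacts such as bright sheets that are not HU-connected to the seed);
#' the vesselness growth suppresses large-caliber structures such as the
#' aorta. The intersection is the robust initial lumen contour.
#'
#' @param volume the HU [coro_volume].
#' @param ves the [frangi_vesselness] image on the same grid.
#' @param seeds seed point(s) at the coronary ostia.
#' @param hu_params [region_grow_params] for the HU image.
#' @param ves_params [region_grow_params] for the vesselness image.
#' @param ves_seeds optional separate seeds for the vesselness growth (e.g.
#'   snapped to the local vesselness ridge); defaults to \code{seeds}.
#' @return A [coro_mask]; guaranteed subset of each input mask.
#' @export
lumen_initial_contour <- function(volume, ves, seeds, hu_params, ves_params,
                                  ves_seeds = seeds) {
  stopifnot_same_grid(volume, ves)
  m_hu <- region_grow(volume, seeds, hu_params)
  m_ves <- region_grow(ves, ves_seeds, ves_params)
  inter <- m_hu$data & m_ves$data
  if (!any(inter))
    stop(paste("lumen initial contour is empty: the HU and vesselness",
               "region-growing masks do not overlap; revise the thresholds"))
  structure(coro_mask(inter, spacing = volume$spacing,
                      origin = volume$origin),
            hu_mask = m_hu, ves_mask = m_ves)
}

#' Outer-wall initial contour (S2): fat-restricted geodesic dilation
#'
#' Extends the segmented lumen by \code{dilation_distance} mm of geodesic
#' (conditional) dilation through the domain of voxels with
#' HU >= \code{fat_hu_threshold} union the lumen itself. Fat regions block
#' propagation (barrier semantics): no added voxel is fat, and no added voxel
#' is geodesically farther than the stated distance from the lumen.
#' Distances are geodesic shortest paths on the 5x5x5 (gcd-reduced) lattice
#' neighbourhood graph with physical (mm) edge lengths (within ~2% of the
#' Euclidean geodesic); long moves are only allowed where a monotone
#' staircase of unit steps stays inside the domain, so the dilation cannot
#' tunnel through a thin fat barrier.
#'
#' @param lumen_final a non-empty lumen [coro_mask].
#' @param volume the HU [coro_volume] on the same grid.
#' @param params an [outer_init_params].
#' @return A [coro_mask] containing the lumen.
#' @export
outer_initial_contour <- function(lumen_final, volume,
                                  params = outer_init_params()) {
  stopifnot_same_grid(lumen_final, volume)
  if (!any(lumen_final$data)) stop("lumen mask is empty")
  domain <- (volume$data >= params$fat_hu_threshold) | lumen_final$data
  dims <- dim(volume$data)
  thr <- params$dilation_distance +
    (if (params$surface_offset) mean(volume$spacing) / 2 else 0)
  gd <- .geodesic_dist_cpp(as.logical(lumen_final$data), as.logical(domain),
                           dims, volume$spacing, NULL, thr * 1.0001,
                           124L, TRUE)
  d <- array(gd$dist, dim = dims)
  out <- is.finite(d) & (d <= thr)
  out <- out | lumen_final$data
  coro_mask(out, spacing = volume$spacing, origin = volume$origin)
}
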