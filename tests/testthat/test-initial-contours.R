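test_that("region growing follows connectivity and thresholds", {
  u <- coro_volume(array(100, c(10, 10, 10)))
  m <- region_grow(u, seed_point(c(5, 5, 5)), region_grow_params(50, 150))
  expect_equal(sum(m$data), 1000)

  # two disjoint in-range blobs: only the seeded one grows
  v <- array(0, c(20, 10, 10))
  v[2:5, 3:6, 3:6] <- 100
  v[12:15, 3:6, 3:6] <- 100
  vol <- coro_volume(v)
  m2 <- region_grow(vol, seed_point(c(3, 4, 4)), region_grow_params(50, 150))
  expect_equal(sum(m2$data), 4^3)
  expect_equal(sum(m2$data[12:15, , ]), 0)

  expect_error(region_grow(vol, seed_point(c(8, 4, 4)),
                           region_grow_params(50, 150)),
               "rejected")
  expect_error(region_grow_params(10, 5), "lower_threshold")
  expect_error(region_grow_params(0, 5, connectivity = 8), "connectivity")
})

test_that("HU region growing recovers the phantom lumen to a voxel shell", {
  ph <- fx_cyl()
  seedp <- seed_point(ph$centerline_points[5, ])
  m <- region_grow(ph$volume, seedp, region_grow_params(200, 600))
  truth <- ph$lumen_mask$data
  expect_equal(sum(truth & !m$data), 0)          # nothing missing
  extra <- m$data & !truth
  # all extra voxels lie within one voxel of the lumen surface
  d <- sqrt(array(coroseg:::.edt_sq_cpp(as.logical(truth), dim(truth),
                                        ph$volume$spacing),
                  dim = dim(truth)))
  expect_lt(max(d[extra], 0), sqrt(3) * 0.4 + 1e-9)
})

test_that("S1 intersection is a subset of both masks and rejects confounders", {
  ph <- fx_cyl()
  pz <- confounder_bright_sheet(ph, offset = 3, hu = 400)
  ves <- frangi_vesselness(pz$volume)
  thr <- stats::quantile(ves$data[ves$data > 0], 0.95, names = FALSE)
  seedp <- seed_point(pz$centerline_points[5, ])
  s1 <- lumen_initial_contour(pz$volume, ves, list(seedp),
                              region_grow_params(175, 800),
                              region_grow_params(thr, Inf))
  expect_true(all(attr(s1, "hu_mask")$data | !s1$data))
  expect_true(all(attr(s1, "ves_mask")$data | !s1$data))
  sheet <- attr(pz, "sheet_mask")$data
  expect_equal(sum(s1$data & sheet), 0)
})

test_that("vesselness suppresses an attached bright reservoir (aorta-like)", {
  ph <- fx_cyl()
  vol <- ph$volume
  # attach a large bright sphere (aorta surrogate) to the tube's proximal end
  ctr <- ph$centerline_points[1, ] + c(0, 0, -2)
  dims <- dim(vol$data)
  ax <- lapply(1:3, function(d) (seq_len(dims[d]) - 1) * 0.4)
  d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
              (ax[[3]] - ctr[3])^2, `+`)
  blob <- d2 <= 6^2
  vol$data[blob] <- 400
  ves <- frangi_vesselness(vol)
  thr <- stats::quantile(ves$data[ves$data > 0], 0.95, names = FALSE)
  seedp <- seed_point(ph$centerline_points[12, ])
  s1 <- lumen_initial_contour(vol, ves, list(seedp),
                              region_grow_params(175, 800),
                              region_grow_params(thr, Inf))
  core <- d2 <= 4^2 & blob          # deep interior of the reservoir
  expect_gt(sum(attr(s1, "hu_mask")$data & core), 0)  # HU growth floods it
  expect_equal(sum(s1$data & core), 0)                # intersection drops it
})

test_that("empty intersection raises an actionable error", {
  # HU blob on the left, vesselness blob on the right, seeds snapped apart:
  # the two growths cannot overlap
  hu <- array(0, c(20, 10, 10)); hu[2:6, 3:7, 3:7] <- 300
  vv <- array(0, c(20, 10, 10)); vv[14:18, 3:7, 3:7] <- 1
  u <- coro_volume(hu)
  ves <- structure(list(data = vv, spacing = u$spacing, origin = u$origin),
                   class = c("coro_vesselness", "coro_volume"))
  expect_error(lumen_initial_contour(u, ves, seed_point(c(3, 4, 4)),
                                     region_grow_params(200, 400),
                                     region_grow_params(0.5, 2),
                                     ves_seeds = seed_point(c(15, 4, 4))),
               "threshold")
})

test_that("restricted dilation matches the independent geodesic oracle", {
  # fat-free fixture
  spk <- phantom_spec(curve_line(12), fat_sheath = FALSE, noise_sigma = 0)
  ph <- make_phantom(spk, shape = c(41, 41, 40), spacing = 0.4)
  prm <- outer_init_params(dilation_distance = 3.0)
  oi <- outer_initial_contour(ph$lumen_mask, ph$volume, prm)
  thr <- 3.0 + mean(ph$volume$spacing) / 2
  domain <- (ph$volume$data >= 0) | ph$lumen_mask$data
  orc <- oracle_geodesic_mask(ph$lumen_mask$data, domain,
                              ph$volume$spacing, thr)
  expect_identical(oi$data, orc | ph$lumen_mask$data)

  # fat-ring fixture: an enclosing negative-HU ring blocks propagation
  hu <- ph$volume
  ring <- !is.na(ph$arclen_field) & ph$dist_field >= 2.0 &
    ph$dist_field <= 2.9
  hu$data[ring] <- -80
  oi2 <- outer_initial_contour(ph$lumen_mask, hu, prm)
  domain2 <- (hu$data >= 0) | ph$lumen_mask$data
  orc2 <- oracle_geodesic_mask(ph$lumen_mask$data, domain2,
                               hu$spacing, thr)
  expect_identical(oi2$data, orc2 | ph$lumen_mask$data)
  # nothing beyond the ring
  expect_lt(max(ph$dist_field[oi2$data]), 2.0)
  # no added voxel is fat
  added <- oi2$data & !ph$lumen_mask$data
  expect_true(all(hu$data[added] >= 0))
})

test_that("dilation radius matches the analytic halo and is monotone", {
  spk <- phantom_spec(curve_line(24), fat_sheath = FALSE, noise_sigma = 0)
  ph <- make_phantom(spk, shape = c(65, 65, 72), spacing = 0.4)
  oi <- outer_initial_contour(ph$lumen_mask, ph$volume)   # default 5.5 mm
  expect_true(all(oi$data | !ph$lumen_mask$data))
  mid <- 30:42
  area <- apply(oi$data[, , mid], 3, sum) * 0.4^2
  expect_lt(abs(mean(area) / (pi * 7.0^2) - 1), 0.05)
  oi2 <- outer_initial_contour(ph$lumen_mask, ph$volume,
                               outer_init_params(dilation_distance = 6.5))
  expect_true(all(oi2$data | !oi$data))     # larger distance only adds
  expect_error(outer_initial_contour(coro_mask(array(FALSE, dim(ph$volume$data)),
                                               grid = ph$volume),
                                     ph$volume),
               "empty")
})
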