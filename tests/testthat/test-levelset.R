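step_volume <- function(delta = 300, n = 33) {
  v <- array(0, c(n, n, n))
  v[, , (n + 1) %/% 2 + (1:((n - 1) %/% 2))] <- delta
  coro_volume(v, spacing = c(0.4, 0.4, 0.4))
}

test_that("feature image is ~1 on homogeneous regions, ~0 at strong edges", {
  cv <- coro_volume(array(55, c(16, 16, 16)))
  f <- compute_feature_image(cv, levelset_params(sigmoid_beta = 20,
                                                 sigmoid_alpha = 1))
  expect_gt(min(f$data), 1 - 1e-6)

  sv <- step_volume()
  fs <- compute_feature_image(sv, levelset_params())
  prof <- fs$data[17, 17, ]
  edge_k <- which.min(prof)
  expect_lt(abs(edge_k - 17.5), 1.01)       # minimum at the step plane
  expect_lt(min(prof), 0.1)
  # the minimum gradient location is the maximum of the smoothed step
  g <- coroseg:::gradient_magnitude(sv, 0.5)
  expect_equal(which.max(g[17, 17, ]), as.integer(round(edge_k)))
})

test_that("feature is monotonically non-increasing in gradient magnitude", {
  sv <- step_volume()
  p <- levelset_params(sigmoid_beta = 100, sigmoid_alpha = 25)
  f <- compute_feature_image(sv, p)
  g <- coroseg:::gradient_magnitude(sv, p$gradient_sigma)
  o <- order(as.numeric(g))
  fo <- as.numeric(f$data)[o]
  expect_true(all(diff(fo) <= 1e-12))
})

test_that("zero feature freezes the contour; truth init is near-fixed-point", {
  ph <- fx_cyl()
  init <- ph$lumen_mask
  f0 <- structure(list(data = array(0, dim(init$data)),
                       spacing = init$spacing, origin = init$origin),
                  class = c("coro_feature", "coro_volume"))
  out <- evolve_level_set(init, f0, levelset_params(max_iterations = 50))
  expect_identical(out$data, init$data)

  p <- levelset_params(max_iterations = 150)
  f <- compute_feature_image(ph$volume, p, init)
  out2 <- evolve_level_set(init, f, p)
  expect_gte(dice_pct(out2, ph$lumen_mask), 98)
  # away from the open tube ends (where rim curvature rounds the cap) the
  # truth mask is an exact fixed point
  A <- ph$arclen_field
  interior <- !is.na(A) & A > 2 & A < 22
  expect_identical(out2$data & interior, ph$lumen_mask$data & interior)
})

test_that("outward evolution recovers an eroded cylinder to ~1 voxel", {
  ph <- fx_cyl()
  phi <- coroseg:::.signed_distance_cpp(as.logical(ph$lumen_mask$data),
                                        dim(ph$lumen_mask$data),
                                        ph$volume$spacing)
  init <- coro_mask(array(phi <= -0.8, dim(ph$lumen_mask$data)),
                    grid = ph$lumen_mask)
  p <- levelset_params(max_iterations = 300)
  f <- compute_feature_image(ph$volume, p, init)
  seg <- evolve_level_set(init, f, p)
  expect_gte(dice_pct(seg, ph$lumen_mask), 88)
  differ <- xor(seg$data, ph$lumen_mask$data)
  if (any(differ)) {
    dtruth <- abs(array(phi, dim(differ)))
    expect_lte(max(dtruth[differ]), sqrt(2) * 0.4 + 1e-9)
  }
  # empty init is a validation error
  expect_error(evolve_level_set(coro_mask(array(FALSE, dim(f$data)),
                                          grid = ph$volume), f, p),
               "empty")
})

test_that("curvature-only flow shrinks a sphere monotonically", {
  n <- 41; h <- 0.4
  ax <- (seq_len(n) - 1) * h - 8
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  sph <- coro_mask(array(d2 <= 16, c(n, n, n)), spacing = rep(h, 3))
  f1 <- structure(list(data = array(1, c(n, n, n)),
                       spacing = rep(h, 3), origin = c(0, 0, 0)),
                  class = c("coro_feature", "coro_volume"))
  vols <- vapply(c(40, 90, 140), function(it) {
    p <- levelset_params(propagation_weight = 0, advection_weight = 0,
                         curvature_weight = 1, max_iterations = it,
                         rms_convergence = 1e-9)
    sum(evolve_level_set(sph, f1, p)$data)
  }, 0.0)
  expect_lt(vols[1], sum(sph$data))
  expect_true(all(diff(vols) < 0))
})

test_that("segment_wall enforces containment and exact set difference", {
  g <- coro_volume(array(0, c(8, 8, 8)))
  a <- coro_mask(array(rep(c(TRUE, FALSE), c(200, 312)), c(8, 8, 8)), grid = g)
  w0 <- segment_wall(a, a)
  expect_equal(sum(w0$wall$data), 0)

  set.seed(3)
  l <- coro_mask(array(runif(512) > 0.7, c(8, 8, 8)), grid = g)
  v <- coro_mask(array(runif(512) > 0.7, c(8, 8, 8)), grid = g)
  w <- segment_wall(l, v)
  expect_true(all(w$vessel$data | !w$lumen$data))
  expect_identical(w$wall$data, w$vessel$data & !w$lumen$data)

  # annulus: 1.5 mm lumen inside a 2.5 mm vessel
  spk <- phantom_spec(curve_line(24), lumen_radius = 1.5,
                      wall_thickness = 1.0, noise_sigma = 0)
  ph <- make_phantom(spk, shape = c(49, 49, 72), spacing = 0.4)
  w2 <- segment_wall(ph$lumen_mask, ph$vessel_mask)
  wall_vol <- sum(w2$wall$data) * voxel_volume(w2$wall)
  expect_lt(abs(wall_vol / (pi * (2.5^2 - 1.5^2) * 24) - 1), 0.05)
})
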