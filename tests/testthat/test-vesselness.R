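# analytic-free tube fixture: bright cylinder radius 2 mm on flat background
tube_vol <- function(axis = "z") {
  spk <- phantom_spec(curve_line(20), lumen_radius = 2, wall_thickness = 0.3,
                      fat_sheath = FALSE, noise_sigma = 0,
                      hu = hu_model(lumen_hu = 400, wall_hu = 40,
                                    myocardium_hu = 40))
  ph <- make_phantom(spk, shape = c(49, 49, 64), spacing = 0.4)
  v <- ph$volume
  if (axis == "x") v$data <- aperm(v$data, c(3, 2, 1))
  v
}

test_that("constant volumes give zero vesselness and range stays in [0,1]", {
  cv <- coro_volume(array(7, c(16, 16, 16)))
  out <- frangi_vesselness(cv, vesselness_params(scales = 1))
  expect_equal(max(out$data), 0)
  ves <- frangi_vesselness(tube_vol(), vesselness_params(scales = c(1, 2)))
  expect_gte(min(ves$data), 0)
  expect_lte(max(ves$data), 1)
})

test_that("Hessian point oracle reproduces analytic second derivatives", {
  g <- coro_volume(array(rep(((0:20) - 10)^2, times = 21 * 21),
                         c(21, 21, 21)))
  ev <- hessian_eigenvalues_at(g, c(10, 10, 10), 1.5)
  expect_lt(max(abs(ev - c(0, 0, 2))), 1e-6)
  g2 <- array(0, c(21, 21, 21))
  for (x in 1:21) for (y in 1:21) g2[x, y, ] <- (x - 11)^2 + (y - 11)^2
  ev2 <- hessian_eigenvalues_at(coro_volume(g2), c(10, 10, 10), 1.5)
  expect_lt(max(abs(ev2 - c(0, 2, 2))), 1e-6)
  cv <- coro_volume(array(3, c(15, 15, 15)))
  expect_lt(max(abs(hessian_eigenvalues_at(cv, c(7, 7, 7), 1))), 1e-9)
  # border proximity is flagged, not silently NaN
  ev3 <- hessian_eigenvalues_at(g, c(1, 10, 10), 1.5)
  expect_false(isTRUE(attr(ev3, "valid")))
  expect_false(any(is.na(ev3)))
})

test_that("tube response peaks near the radius and beats a blob", {
  vol <- tube_vol()
  prm <- vesselness_params(scales = c(1, 2, 3))
  ves <- frangi_vesselness(vol, prm)
  ctr <- c(25, 25, 32)
  expect_equal(ves$scale_of_max[ctr[1], ctr[2], ctr[3]], 2)

  # oracle: compute the Frangi measure by hand from the point Hessian
  frangi_from_eigs <- function(ev, c2) {
    ev <- ev[order(abs(ev))]
    if (ev[2] > 0 || ev[3] > 0) return(0)
    Ra <- abs(ev[2]) / abs(ev[3])
    Rb <- abs(ev[1]) / sqrt(abs(ev[2] * ev[3]))
    S2 <- sum(ev^2)
    (1 - exp(-Ra^2 / (2 * 0.5^2))) * exp(-Rb^2 / (2 * 0.5^2)) *
      (1 - exp(-S2 / (2 * c2^2)))
  }
  # same c as the filter used: recover it by inverting the S term is
  # overkill; instead fix c explicitly in both paths
  prm_fixed <- vesselness_params(scales = 2, c = 500)
  ves_fixed <- frangi_vesselness(vol, prm_fixed)
  ev <- hessian_eigenvalues_at(vol, ctr - 1L, 2) * 4   # sigma^2 gamma-norm
  expect_equal(ves_fixed$data[ctr[1], ctr[2], ctr[3]],
               frangi_from_eigs(ev, 500), tolerance = 1e-6)

  # a bright sphere of the same HU responds several-fold less at its center
  h <- 0.4
  ax <- (seq_len(49) - 1) * h - 9.6
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  svol <- coro_volume(array(ifelse(d2 <= 4, 400, 40), c(49, 49, 49)),
                      rep(h, 3))
  vs <- frangi_vesselness(svol, prm)
  ic <- which.min(abs(ax))
  ratio <- ves$data[ctr[1], ctr[2], ctr[3]] / max(vs$data[ic, ic, ic], 1e-12)
  expect_gt(ratio, 5)
})

test_that("polarity gate zeroes the response for inverted contrast", {
  vol <- tube_vol()
  vol$data <- 440 - vol$data              # dark tube on bright background
  ves <- frangi_vesselness(vol, vesselness_params(scales = c(1, 2),
                                                  bright_on_dark = TRUE))
  expect_equal(ves$data[25, 25, 32], 0)
})

test_that("vesselness is rotation invariant between axis-aligned tubes", {
  vz <- frangi_vesselness(tube_vol("z"), vesselness_params(scales = c(1, 2)))
  vx <- frangi_vesselness(tube_vol("x"), vesselness_params(scales = c(1, 2)))
  # matched voxels on the two axes, away from the ends
  az <- vz$data[25, 25, 20:44]
  axx <- vx$data[20:44, 25, 25]
  expect_lt(max(abs(az - axx)) / max(az), 0.02)
})

test_that("extreme alpha/beta reduce the response to the structureness term", {
  # alpha -> 0 sends the plate/line gate to 1 (for Ra > 0); beta -> Inf
  # sends the blob gate to 1; what remains is the structureness term
  vol <- tube_vol()
  prm <- vesselness_params(scales = 2, alpha = 1e-6, beta = 1e6, c = 500)
  ves <- frangi_vesselness(vol, prm)
  ev <- hessian_eigenvalues_at(vol, c(24, 24, 31), 2) * 4
  expect_equal(ves$data[25, 25, 32], 1 - exp(-sum(ev^2) / (2 * 500^2)),
               tolerance = 1e-4)
})

test_that("scale and size validation errors fire", {
  expect_error(vesselness_params(scales = numeric(0)), "scales")
  expect_error(vesselness_params(alpha = 0), "alpha")
  small <- coro_volume(array(rnorm(4^3), c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(frangi_vesselness(small, vesselness_params(scales = 5)),
               "too small")
})
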