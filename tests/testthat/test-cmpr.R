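test_that("straightened straight tube has constant analytic disc sections", {
  ph <- fx_cyl()
  cl <- fx_cyl_centerline()
  st <- straighten(ph$lumen_mask, cl, half_width = 5)
  areas <- apply(st$data > 0.5, 1, sum) * st$in_plane_step^2
  sel <- 10:(length(areas) - 10)
  expect_lt(max(abs(areas[sel] / (pi * 1.5^2) - 1)), 0.05)

  # centerline-column HU equals the axis profile within interpolation noise
  sv <- straighten(ph$volume, cl, half_width = 5)
  ctr_col <- sv$data[sel, (dim(sv$data)[2] + 1) / 2, (dim(sv$data)[3] + 1) / 2]
  expect_lt(max(abs(ctr_col - 400)), 1)
})

test_that("CMPR is curvature-invariant: torus sections stay constant", {
  ph <- fx_torus_fine()
  cp <- ph$centerline_points
  cl <- extract_centerline(ph$lumen_mask, seed_point(cp[2, ]),
                           seed_point(cp[nrow(cp) - 1, ]))
  st <- straighten(ph$lumen_mask, cl, half_width = 5)
  areas <- apply(st$data > 0.5, 1, sum) * st$in_plane_step^2
  sel <- 8:(length(areas) - 8)
  rel <- areas[sel] / mean(areas[sel]) - 1
  expect_lt(max(abs(rel)), 0.07)
})

test_that("CMPR of masks is idempotent in shape and conserves volume", {
  ph <- fx_cyl()
  cl <- fx_cyl_centerline()
  st <- straighten(ph$lumen_mask, cl, half_width = 5)
  areas <- apply(st$data > 0.5, 1, sum) * st$in_plane_step^2
  sel <- 10:(length(areas) - 10)
  # straightening an already-straight tube reproduces the direct per-slice
  # areas of the mask; the two boundary conventions (voxel-center counting
  # vs sub-voxel midpoint crossing) differ by up to ~half a voxel of radius
  direct <- apply(ph$lumen_mask$data, 3, sum) * prod(ph$volume$spacing[1:2])
  dsel <- direct[direct > 0]
  dsel <- dsel[5:(length(dsel) - 5)]
  expect_lt(abs(mean(areas[sel]) / mean(dsel) - 1), 0.03)
  # and matches the analytic section closely
  expect_lt(abs(mean(areas[sel]) / (pi * 1.5^2) - 1), 0.02)
  step <- mean(diff(cl$arc_length))
  integ <- sum(areas) * step
  direct <- sum(ph$lumen_mask$data) * voxel_volume(ph$lumen_mask)
  expect_lt(abs(integ / direct - 1), 0.10)
})

test_that("radial sections honor the protocol angles", {
  ph <- fx_cyl()
  cl <- fx_cyl_centerline()
  st <- straighten(ph$lumen_mask, cl, half_width = 5)
  s5 <- radial_sections(st, 5)
  expect_length(s5, 5)
  expect_equal(attr(s5, "angular_gap_deg"), 36)
  s20 <- radial_sections(st, 20)
  expect_length(s20, 20)
  expect_equal(attr(s20, "angular_gap_deg"), 9)
  # rotational symmetry of a straight tube: all sections agree
  sel <- 10:(dim(st$data)[1] - 10)
  for (k in 2:5)
    expect_lt(mean(s5[[1]][sel, ] != s5[[k]][sel, ]), 0.05)
  # a section 180 degrees away is the mirrored section
  tt <- seq(-st$half_width, st$half_width, by = st$in_plane_step)
  a0 <- coroseg:::sample_slice(st$data[30, , ], st$half_width,
                               st$in_plane_step, tt * cos(0.6),
                               tt * sin(0.6), nearest = TRUE)
  a180 <- coroseg:::sample_slice(st$data[30, , ], st$half_width,
                                 st$in_plane_step, tt * cos(0.6 + pi),
                                 tt * sin(0.6 + pi), nearest = TRUE)
  expect_identical(a0, rev(a180))
})

test_that("wall thickness profile recovers annulus and healthy thickness", {
  ph <- fx_cyl()                      # healthy 0.75 mm wall
  cl <- fx_cyl_centerline()
  stl <- straighten(ph$lumen_mask, cl, half_width = 5)
  stv <- straighten(ph$vessel_mask, cl, half_width = 5)
  wt <- wall_thickness_profile(stl, stv)
  sel <- 10:(nrow(wt) - 10)
  expect_lt(abs(mean(wt$mean_thickness[sel]) - 0.75), stl$in_plane_step / 2)
  expect_true(all(wt$vessel_area >= wt$lumen_area))

  spk <- phantom_spec(curve_line(24), lumen_radius = 1.5,
                      wall_thickness = 1.0, noise_sigma = 0)
  ph2 <- make_phantom(spk, shape = c(49, 49, 72), spacing = 0.4)
  cl2 <- extract_centerline(ph2$lumen_mask,
                            seed_point(ph2$centerline_points[2, ]),
                            seed_point(ph2$centerline_points[nrow(ph2$centerline_points) - 1, ]))
  wt2 <- wall_thickness_profile(straighten(ph2$lumen_mask, cl2, half_width = 5),
                                straighten(ph2$vessel_mask, cl2, half_width = 5))
  expect_lt(abs(mean(wt2$mean_thickness[sel]) - 1.0), 0.1)

  # lumen == vessel means zero thickness
  wt3 <- wall_thickness_profile(stl, stl)
  expect_true(all(wt3$mean_thickness[!wt3$missing] == 0))
})

test_that("slices with no lumen at the center are flagged missing", {
  ph <- fx_cyl()
  cl <- fx_cyl_centerline()
  stl <- straighten(ph$lumen_mask, cl, half_width = 5)
  stv <- straighten(ph$vessel_mask, cl, half_width = 5)
  stl$data[5, , ] <- 0                 # simulate an occluded slice
  wt <- wall_thickness_profile(stl, stv)
  expect_true(wt$missing[5])
  expect_true(is.na(wt$mean_thickness[5]))
})
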