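sphere_mask <- function(r = 5, h = 0.4, n = 40) {
  ax <- (seq_len(n) - 1) * h
  ctr <- (n - 1) * h / 2
  d2 <- outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`)
  coro_mask(array(d2 <= r^2, c(n, n, n)), spacing = rep(h, 3))
}

test_that("sphere mesh matches analytic area, volume, and topology", {
  msh <- extract_mesh(sphere_mask())
  expect_lt(abs(mesh_area(msh) / (4 * pi * 25) - 1), 0.05)
  expect_lt(abs(mesh_volume(msh) / (4 / 3 * pi * 125) - 1), 0.03)
  expect_equal(mesh_euler(msh), 2)
})

test_that("meshes are watertight with no degenerate faces", {
  msh <- extract_mesh(sphere_mask(r = 3, n = 24))
  F <- msh$faces
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(ek) == 2))          # every edge shared by 2 faces
  V <- msh$vertices
  a <- V[F[, 2], ] - V[F[, 1], ]
  b <- V[F[, 3], ] - V[F[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  expect_gt(min(sqrt(rowSums(cr^2)) / 2), 1e-9)
  expect_error(extract_mesh(coro_volume(array(1, c(8, 8, 8))), level = 5),
               "range")
})

test_that("mesh export writes valid PLY and STL text", {
  msh <- extract_mesh(sphere_mask(r = 2.5, n = 20))
  fp <- tempfile(fileext = ".ply")
  write_mesh(msh, fp)
  head <- readLines(fp, n = 2)
  expect_equal(head[1], "ply")
  fs <- tempfile(fileext = ".stl")
  write_mesh(msh, fs)
  expect_true(grepl("^solid", readLines(fs, n = 1)))
})

test_that("straight-cylinder centerline rides the axis with correct radius", {
  ph <- fx_cyl()
  cl <- fx_cyl_centerline()
  axis_xy <- ph$centerline_points[1, 1:2]
  dev <- sqrt((cl$points[, 1] - axis_xy[1])^2 +
                (cl$points[, 2] - axis_xy[2])^2)
  expect_lt(max(dev), 0.5 * max(ph$volume$spacing))
  interior <- cl$arc_length > 2 & cl$arc_length < max(cl$arc_length) - 2
  expect_lt(max(abs(cl$max_inscribed_radius[interior] - 1.5)), 0.2 + 1e-9)
  # points are interior to the lumen
  phi <- array(coroseg:::.signed_distance_cpp(as.logical(ph$lumen_mask$data),
                                              dim(ph$lumen_mask$data),
                                              ph$volume$spacing),
               dim = dim(ph$lumen_mask$data))
  sphi <- coroseg:::.sample_volume_cpp(as.numeric(phi), dim(phi),
                                       ph$volume$spacing, ph$volume$origin,
                                       cl$points, 0L, 1)$values
  expect_lt(max(sphi), 0)
})

test_that("quarter-torus centerline length matches the analytic arc", {
  ph <- fx_torus()
  cp <- ph$centerline_points
  cl <- extract_centerline(ph$lumen_mask, seed_point(cp[2, ]),
                           seed_point(cp[nrow(cp) - 1, ]))
  expect_lt(abs(max(cl$arc_length) - pi / 2 * 20) / (pi / 2 * 20), 0.03)
})

test_that("a mesh can seed centerline extraction via its source mask", {
  ph <- fx_cyl()
  msh <- extract_mesh(ph$lumen_mask, provenance = "lumen")
  s <- phantom_seeds(ph, off = 2)
  cl <- extract_centerline(msh, s[[1]], s[[2]])
  expect_gt(nrow(cl$points), 10)
  expect_error(extract_centerline(msh, seed_point(c(0.4, 0.4, 0.4)),
                                  s[[2]]),
               "not inside")
})

test_that("disconnected lumen interiors give a no-path error", {
  v <- array(FALSE, c(15, 15, 31))
  v[6:10, 6:10, 2:12] <- TRUE
  v[6:10, 6:10, 20:30] <- TRUE
  m <- coro_mask(v, spacing = c(0.4, 0.4, 0.4))
  expect_error(extract_centerline(m, seed_point(c(2.8, 2.8, 2)),
                                  seed_point(c(2.8, 2.8, 10))),
               "disconnected")
})

test_that("helix frames recover the analytic curvature", {
  t <- seq(0, 2 * pi, by = 0.02)
  P <- cbind(10 * cos(t), 10 * sin(t), 3 * t)
  al <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  cl <- compute_frames(structure(list(points = P, arc_length = al),
                                 class = "coro_centerline"))
  interior <- 10:(length(t) - 10)
  kap <- cl$curvature[interior]
  expect_lt(max(abs(kap - 10 / 109)) / (10 / 109), 0.02)
})

test_that("straight-line frames fall back to parallel transport", {
  P <- cbind(0, 0, seq(0, 10, by = 0.25))
  al <- P[, 3]
  cl <- compute_frames(structure(list(points = P, arc_length = al),
                                 class = "coro_centerline"))
  expect_false(any(is.na(cl$normal)))
  expect_lt(max(abs(sweep(cl$tangent, 2, c(0, 0, 1)))), 1e-9)
  expect_lt(max(abs(sweep(cl$normal, 2, cl$normal[1, ]))), 1e-9)
  expect_error(compute_frames(structure(list(points = P[c(1, 1, 2), ],
                                             arc_length = c(0, 0, 1)),
                                        class = "coro_centerline")),
               "duplicate")
})

test_that("frames are orthonormal and continuous on all test curves", {
  curves <- list(fx_cyl_centerline(), {
    t <- seq(0, 4, by = 0.02)
    P <- cbind(8 * cos(t), 8 * sin(t), 2 * t)
    compute_frames(structure(list(points = P,
                                  arc_length = c(0, cumsum(sqrt(rowSums(diff(P)^2))))),
                             class = "coro_centerline"))
  })
  for (cl in curves) {
    ortho <- abs(rowSums(cl$tangent * cl$normal)) +
      abs(rowSums(cl$tangent * cl$binormal)) +
      abs(rowSums(cl$normal * cl$binormal))
    expect_lt(max(ortho), 1e-6)
    lens <- c(rowSums(cl$tangent^2), rowSums(cl$normal^2),
              rowSums(cl$binormal^2))
    expect_lt(max(abs(lens - 1)), 1e-6)
    ang <- acos(pmin(1, rowSums(cl$normal[-1, ] * cl$normal[-nrow(cl$normal), ])))
    expect_lt(max(ang), 30 * pi / 180)
  }
})

test_that("centerline TSV export has the documented columns", {
  cl <- fx_cyl_centerline()
  f <- tempfile(fileext = ".tsv")
  write_centerline(cl, f)
  df <- utils::read.delim(f)
  expect_equal(names(df),
               c("x", "y", "z", "arclen", "Tx", "Ty", "Tz",
                 "Nx", "Ny", "Nz", "Bx", "By", "Bz", "radius"))
  expect_equal(nrow(df), nrow(cl$points))
})
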