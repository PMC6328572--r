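# Shared fixtures, built once per test run and cached. All phantoms are
# generated in code; nothing is read from disk.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

dice_pct <- function(a, b) {
  if (inherits(a, "coro_mask")) a <- a$data
  if (inherits(b, "coro_mask")) b <- b$data
  200 * sum(a & b) / (sum(a) + sum(b))
}

# straight healthy tube, noise-free, odd dims so the axis hits voxel centers
fx_cyl <- function() fx("cyl", function() {
  make_phantom(phantom_spec(curve_line(24), noise_sigma = 0),
               shape = c(49, 49, 72), spacing = 0.4)
})

# quarter-torus tube (ring radius 20 mm)
fx_torus <- function() fx("torus", function() {
  make_phantom(phantom_spec(curve_arc(radius = 20, angle = pi / 2),
                            noise_sigma = 0),
               shape = c(91, 41, 91), spacing = 0.4)
})

fx_torus_fine <- function() fx("torus_fine", function() {
  make_phantom(phantom_spec(curve_arc(radius = 20, angle = pi / 2),
                            noise_sigma = 0),
               shape = c(121, 55, 121), spacing = 0.3)
})

# curved tube with one 50% soft-plaque stenosis (the end-to-end benchmark)
fx_plaque_spec <- function(noise)
  phantom_spec(curve_arc(radius = 30, angle = 0.9),
               plaques = list(plaque_spec(10, 6, "soft",
                                          max_wall_thickening = 1.2,
                                          lumen_narrowing_fraction = 0.5)),
               noise_sigma = noise)

fx_plaque_clean <- function() fx("plaque_clean", function()
  make_phantom(fx_plaque_spec(0), shape = c(80, 56, 80), spacing = 0.4))

fx_plaque_noisy <- function() fx("plaque_noisy", function()
  make_phantom(fx_plaque_spec(20), shape = c(80, 56, 80), spacing = 0.4))

# motion-blur gap phantom: a 5 mm window of strong local blur
fx_gap <- function() fx("gap", function()
  make_phantom(phantom_spec(curve_line(34),
                            motion_blur = list(window = c(14, 19),
                                               sigma = 1.5,
                                               transition = 0.75),
                            noise_sigma = 20),
               shape = c(56, 56, 92), spacing = 0.4))

phantom_seeds <- function(ph, off = 4) {
  n <- nrow(ph$centerline_points)
  list(seed_point(ph$centerline_points[off, ]),
       seed_point(ph$centerline_points[n - off + 1, ]))
}

run_cached <- function(name, ph, ..., seeds = NULL) {
  fx(name, function() {
    if (is.null(seeds)) seeds <- phantom_seeds(ph)
    run_pipeline(ph$volume, seeds, ...)
  })
}

fx_run_clean <- function() run_cached("run_clean", fx_plaque_clean())
fx_run_clean2 <- function() fx("run_clean2", function() {
  ph <- fx_plaque_clean()
  run_pipeline(ph$volume, phantom_seeds(ph))
})
fx_run_noisy <- function() run_cached("run_noisy", fx_plaque_noisy())
fx_run_gap <- function() run_cached("run_gap", fx_gap())
fx_run_gap_baseline <- function() fx("run_gap_base", function() {
  ph <- fx_gap()
  run_pipeline(ph$volume, phantom_seeds(ph), init_mode = "seed_sphere")
})

# straight-tube centerline reused by cmpr tests
fx_cyl_centerline <- function() fx("cyl_cl", function() {
  ph <- fx_cyl()
  s <- phantom_seeds(ph, off = 2)
  extract_centerline(ph$lumen_mask, s[[1]], s[[2]])
})

# independent plain-R geodesic distance oracle: Bellman-Ford relaxation on
# the same neighbourhood/support semantics as the package implementation,
# but written entirely separately (vectorized array shifts, no Dijkstra)
oracle_geodesic_mask <- function(source, domain, spacing, thr) {
  dims <- dim(domain)
  offs <- list()
  for (z in -2:2) for (y in -2:2) for (x in -2:2) {
    if (x == 0 && y == 0 && z == 0) next
    if (gcd3(abs(x), abs(y), abs(z)) != 1) next
    offs[[length(offs) + 1]] <- c(x, y, z)
  }
  shift_arr <- function(a, v, fill) {
    out <- array(fill, dim = dims)
    sx <- seq_len(dims[1]); sy <- seq_len(dims[2]); sz <- seq_len(dims[3])
    fx_ <- sx - v[1]; fy <- sy - v[2]; fz <- sz - v[3]
    okx <- fx_ >= 1 & fx_ <= dims[1]
    oky <- fy >= 1 & fy <= dims[2]
    okz <- fz >= 1 & fz <= dims[3]
    out[sx[okx], sy[oky], sz[okz]] <- a[fx_[okx], fy[oky], fz[okz]]
    out
  }
  # monotone-staircase support: M(v)[a] = TRUE iff some axis step e keeps
  # a+e in-domain and M(v-e)[a+e]
  memo <- new.env(parent = emptyenv())
  M <- function(v) {
    key <- paste(v, collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (all(v == 0)) {
      res <- array(TRUE, dim = dims)
    } else {
      res <- array(FALSE, dim = dims)
      for (d in 1:3) {
        if (v[d] == 0) next
        e <- c(0, 0, 0); e[d] <- sign(v[d])
        ok_next <- shift_arr(domain & M(v - e), -e, FALSE)
        res <- res | ok_next
      }
    }
    memo[[key]] <- res
    res
  }
  dist <- array(Inf, dim = dims)
  dist[source & domain] <- 0
  lens <- vapply(offs, function(v) sqrt(sum((v * spacing)^2)), 0.0)
  repeat {
    changed <- FALSE
    for (k in seq_along(offs)) {
      v <- offs[[k]]
      cand <- shift_arr(dist, v, Inf) + lens[k]
      sup <- shift_arr(M(v), v, FALSE)
      upd <- domain & sup & (cand < dist)
      if (any(upd)) {
        dist[upd] <- cand[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  (dist <= thr) | source
}

gcd2 <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}
gcd3 <- function(a, b, c) gcd2(gcd2(a, b), c)
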