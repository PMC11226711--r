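test_that("green0 matches reference values and the asymptotic form", {
  # H0^(1)(1) = 0.765198 + 0.088258i  =>  -(i/4) H0^(1)(1)
  expect_equal(green0(1, 1), 0.022064 - 0.191300i, tolerance = 1e-4)
  g100 <- green0(1, 100)
  asym <- -0.25i * sqrt(2 / (pi * 100)) * exp(1i * (100 - pi / 4))
  expect_lt(Mod(g100 - asym) / Mod(asym), 0.01)
  expect_lt(Mod(green0(2, 10 / 2)), Mod(green0(2, 1 / 2)))
  expect_error(green0(1, 0), "d > 0")
  expect_error(green0(0, 1), "positive")
})

test_that("operator assembly is symmetric with the contracted quadratures", {
  cfg <- small_config()
  grid <- build_grid(cfg, cfg$N1)
  lay <- build_layout(cfg)
  k <- 2 * pi * cfg$f1 / cfg$c0

  ops <- assemble_green_operators(grid, lay, k)   # midpoint, zero self cell
  expect_identical(ops$C, t(ops$C))
  expect_true(all(diag(ops$C) == 0))
  expect_true(all(is.finite(Mod(ops$C))))
  expect_equal(dim(ops$B), c(cfg$Nr, grid$N^2))
  # midpoint entries are exactly green0 * h^2
  expect_equal(ops$C[1, 2],
               grid$h^2 * green0(k, sqrt(sum((grid$centers[1, ] -
                                              grid$centers[2, ])^2))))

  opsd <- assemble_green_operators(grid, lay, k, quadrature = "disk",
                                   self_cell = "disk")
  d <- diag(opsd$C)
  expect_true(all(is.finite(Mod(d))))
  expect_equal(max(Mod(d - d[1])), 0)            # translation invariance
  # disk quadrature tends to the midpoint rule as k*h -> 0
  ksmall <- 0.05 / grid$h
  m <- assemble_green_operators(grid, lay, ksmall)
  dd <- assemble_green_operators(grid, lay, ksmall, quadrature = "disk")
  off <- row(m$C) != col(m$C)
  expect_lt(max(Mod(dd$C[off] - m$C[off]) / Mod(m$C[off])), 0.01)

  expect_error(assemble_green_operators(grid, lay, 2 * pi / grid$h),
               "too coarse")
})

test_that("incident Bessel beams behave like J0 of the wavenumber-distance", {
  cfg <- small_config()
  grid <- build_grid(cfg, cfg$N2)
  lay <- build_layout(cfg)
  k0 <- 2 * pi * cfg$f1 / cfg$c0
  f <- incident_field(lay, grid, k0, 1)
  expect_true(all(abs(f) <= 1 + 1e-12))
  d <- sqrt(colSums((t(grid$centers) - lay$transmitter_positions[1, ])^2))
  expect_equal(f, besselJ(k0 * d, 0), tolerance = 1e-12)
  # first root of J0
  expect_lt(abs(besselJ(2.404826, 0)), 1e-5)
  expect_error(incident_field(lay, grid, k0, 99), "out of range")
})

test_that("the exact total-field solve honors its residual contract", {
  cfg <- small_config()
  grid <- build_grid(cfg, cfg$N2)
  lay <- build_layout(cfg)
  k0 <- 2 * pi * cfg$f2 / cfg$c0
  ops <- assemble_green_operators(grid, lay, k0)
  ph <- small_phantom(cfg)
  G <- object_function(ph, cfg$f2)
  inc <- incident_field(lay, grid, k0, 1)

  expect_equal(solve_total_field(ops, rep(0, grid$N^2), inc), inc + 0i,
               tolerance = 1e-14, ignore_attr = TRUE)
  tot <- solve_total_field(ops, G, inc)
  n <- grid$N^2
  A <- diag(n) - ops$C * matrix(G, n, n, byrow = TRUE)
  expect_lt(vnorm(A %*% tot - inc), 1e-10 * vnorm(inc))
  # re-substituting the solution changes nothing
  expect_lt(vnorm(solve_total_field(ops, G, inc) - tot), 1e-12 * vnorm(tot))
})

test_that("Born recursion agrees with the exact solve to second order", {
  cfg <- small_config()
  grid <- build_grid(cfg, cfg$N2)
  lay <- build_layout(cfg)
  k0 <- 2 * pi * cfg$f2 / cfg$c0
  ops <- assemble_green_operators(grid, lay, k0)
  ph <- small_phantom(cfg)
  G <- object_function(ph, cfg$f2)
  inc <- incident_field(lay, grid, k0, 1)
  errs <- vapply(c(1e-2, 5e-3, 2.5e-3), function(eps) {
    vnorm(solve_total_field(ops, eps * G, inc) -
          born_total_field(ops, eps * G, inc))
  }, numeric(1))
  expect_equal(errs[1] / errs[2], 4, tolerance = 0.1)
  expect_equal(errs[2] / errs[3], 4, tolerance = 0.1)
})

test_that("predicted scattering equals the brute-force pixel sum", {
  cfg <- small_config()
  grid <- build_grid(cfg, cfg$N2)
  lay <- build_layout(cfg)
  k0 <- 2 * pi * cfg$f2 / cfg$c0
  ops <- assemble_green_operators(grid, lay, k0)
  n <- grid$N^2
  set.seed(11)
  G <- complex(real = rnorm(n), imaginary = rnorm(n)) * 1e6
  tot <- complex(real = rnorm(n), imaginary = rnorm(n))

  expect_equal(predict_scattered(ops, rep(0, n), tot), rep(0i, cfg$Nr))
  got <- predict_scattered(ops, G, tot)
  oracle <- vapply(seq_len(cfg$Nr), function(r) {
    s <- 0i
    for (j in seq_len(n)) s <- s + ops$B[r, j] * G[j] * tot[j]
    s
  }, complex(1))
  expect_equal(got, oracle, tolerance = 1e-12)

  Gj <- rep(0i, n); Gj[17] <- 3 + 2i
  expect_equal(predict_scattered(ops, Gj, tot),
               as.vector(ops$B[, 17] * Gj[17] * tot[17]), tolerance = 1e-12)
})

test_that("additive noise is deterministic and correctly scaled", {
  set.seed(3)
  v <- complex(real = rnorm(1e4), imaginary = rnorm(1e4)) * 0.1
  expect_identical(add_noise(v, 0, 1L), v)
  expect_identical(add_noise(v, 0.1, 42L), add_noise(v, 0.1, 42L))
  expect_false(identical(add_noise(v, 0.1, 42L), add_noise(v, 0.1, 43L)))
  nse <- add_noise(v, 0.1, 7L) - v
  target <- 0.1 * sqrt(mean(Mod(v)^2))
  expect_equal(sqrt(mean(Mod(nse)^2)), target, tolerance = 0.05)
  # RNG state of the session is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(add_noise(v, 0.1, 1L)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("measurement sweeps stack transmitter-major with per-frequency noise", {
  cfg <- scenario_config(noise_pct = 0)
  grid <- build_grid(cfg, cfg$N2)
  lay <- build_layout(cfg)
  ph <- make_single_disk(grid, cfg$disk_diameter, cfg$contrast_pct, cfg$c0)
  m2 <- simulate_measurements(ph, cfg, lay, cfg$f2)
  expect_length(m2$values, 472L)

  zero <- make_single_disk(grid, cfg$disk_diameter, 0, cfg$c0)
  expect_true(all(simulate_measurements(zero, cfg, lay, cfg$f1)$values == 0))

  m1 <- simulate_measurements(ph, cfg, lay, cfg$f1)
  expect_gt(vnorm(m1$values - m2$values), 0)

  # transmitter-major stacking: first Nr values belong to transmitter 1
  k0 <- 2 * pi * cfg$f2 / cfg$c0
  ops <- assemble_green_operators(grid, lay, k0)
  G <- object_function(ph, cfg$f2)
  tot1 <- born_total_field(ops, G, incident_field(lay, grid, k0, 1))
  expect_equal(m2$values[seq_len(cfg$Nr)],
               predict_scattered(ops, G, as.vector(tot1)), tolerance = 1e-10)
})

test_that("reciprocity holds for a centered disk with equal-radius probes", {
  # probe angles multiples of 90 degrees so the reflection symmetry of the
  # square pixel lattice applies exactly
  cfg <- scenario_config(f1 = 5e5, f2 = 1e6, N1 = 5, N2 = 10, Nt = 4,
                         Nr = 4, Rt = 0.05, Rr = 0.05, noise_pct = 0)
  grid <- build_grid(cfg, cfg$N2)
  ph <- small_phantom(cfg)
  ang <- (seq_len(4) - 1) * pi / 2
  pts <- 0.05 * cbind(cos(ang), sin(ang))
  lay <- uctborn:::new_layout(pts, pts)
  m <- simulate_measurements(ph, cfg, lay, cfg$f2, noise_pct = 0)
  vals <- matrix(m$values, nrow = 4, byrow = TRUE)   # [transmitter, receiver]
  expect_equal(vals, t(vals), tolerance = 1e-8)
})

test_that("measurement files round-trip exactly", {
  cfg <- small_config()
  grid <- build_grid(cfg, cfg$N2)
  lay <- build_layout(cfg)
  ph <- small_phantom(cfg)
  m <- simulate_measurements(ph, cfg, lay, cfg$f2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  expect_identical(back$values, m$values)
  expect_equal(back[c("frequency", "Nt", "Nr", "noise_pct", "seed")],
               m[c("frequency", "Nt", "Nr", "noise_pct", "seed")])
})
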