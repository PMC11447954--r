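test_that("frame weights: gauge invariance and bias reweighting", {
  tr <- list(bias = rep(0, 100), potential = rnorm(100), temperature = 310)
  expect_equal(frameWeights(tr), rep(1, 100))
  tr$bias <- rep(7.3, 100)
  expect_equal(frameWeights(tr), rep(1, 100))
  ## shift invariance: adding a constant to all biases changes nothing
  tr$bias <- runif(100, 0, 5)
  w1 <- frameWeights(tr)
  tr2 <- tr; tr2$bias <- tr$bias + 123.4
  expect_equal(frameWeights(tr2), w1, tolerance = 1e-12)
  expect_error(frameWeights(list(potential = 1, temperature = 310)), "bias")
})

test_that("fesNd: flat for uniform samples, weight-scale invariant, degenerate warnings", {
  set.seed(8)
  u <- runif(20000, -1, 1)
  g <- seq(-0.9, 0.9, length.out = 19)
  f <- fesNd(u, grid = g, temperature = 310)
  expect_lt(max(freeEnergy(f), na.rm = TRUE), 3 * max(uncertainty(f), na.rm = TRUE) + 0.05)
  ## doubling all weights changes nothing
  w <- runif(length(u), 0.5, 2)
  f1 <- fesNd(u, w, g, temperature = 310)
  f2 <- fesNd(u, 2 * w, g, temperature = 310)
  expect_equal(freeEnergy(f1), freeEnergy(f2), tolerance = 1e-12)
  expect_warning(fesNd(rep(0, 50), grid = g, temperature = 310, nBoot = 0),
                 "single bin")
  expect_error(fesNd(rep(99, 5), grid = g, temperature = 310), "inside")
})

test_that("basin analysis: symmetry, programmed depth, monotone flag, minima mode", {
  g <- seq(-2.2, 2.2, length.out = 221)
  sym <- analyticFes(doubleWellSpec(barrier = 10), "x", g, 310)
  b <- basinAnalysis(sym, c(0.1, 2.2), c(-2.2, -0.1))
  expect_lt(abs(deltaG(b)), 0.02)
  expect_equal(b@barrierLocation, 0, tolerance = 0.03)

  ## programmed 10 kJ/mol depth difference through the 2D quadrature oracle
  ins <- analyticFes(insertionSpec(barrier = 12, deltaG = -10,
                                   coupling = 0.3), "s", g, 310)
  bi <- basinAnalysis(ins, c(0.1, 2.2), c(-2.2, -0.1))
  expect_lt(abs(deltaG(bi) + 10), 0.2)
  ## minima-difference mode approximates the integral mode for deep wells
  bm <- basinAnalysis(ins, c(0.1, 2.2), c(-2.2, -0.1), method = "minima")
  expect_lt(abs(deltaG(bm) - deltaG(bi)), 0.6)

  ## monotone profile: barrier 0 with a flag
  F <- seq(0, 5, length.out = 51)
  mono <- new("FreeEnergySurface", grid = list(seq(-1, 1, length.out = 51)),
              values = array(F), se = array(0 * F), ess = array(F * 0 + 10),
              cvNames = "x", cvUnits = "nm", temperature = 310,
              metadata = list())
  bmono <- basinAnalysis(mono, c(-1, -0.5), c(0.5, 1))
  expect_equal(barrierHeight(bmono), 0)
  expect_true("monotone" %in% bmono@flags)
  expect_error(basinAnalysis(mono, c(-1, 0.2), c(0, 1)), "disjoint")
})

test_that("projection comparison: identity, barrier underestimation, zero-coupling limit", {
  g <- seq(-2.6, 2.6, length.out = 209)
  spec <- insertionSpec(barrier = 10, deltaG = -6, coupling = 0.8, kOrth = 20)
  fz <- analyticFes(spec, "x", g, 310)
  fs <- analyticFes(spec, "s", g, 310)
  rng <- list(A = c(0.25, 2.6), B = c(-2.6, -0.25))

  ## same surface twice: identical entries
  same <- compareCvFes(fz, fz, rng, rng)
  expect_identical(same$dG_z, same$dG_cv)
  expect_identical(same$barrier_z, same$barrier_cv)

  cmp <- compareCvFes(fz, fs, rng, rng)
  ## dG is path independent (exact quadrature: sub-0.3 kJ/mol agreement)
  expect_lt(cmp$dG_difference, 0.3)
  ## the bare-x projection underestimates the barrier
  expect_gt(cmp$barrier_cv, cmp$barrier_z + 1)

  ## zero coupling: the projections coincide
  spec0 <- insertionSpec(barrier = 10, deltaG = -6, coupling = 0, kOrth = 20)
  f0z <- analyticFes(spec0, "x", g, 310)
  f0s <- analyticFes(spec0, "s", g, 310)
  cmp0 <- compareCvFes(f0z, f0s, rng, rng)
  expect_lt(abs(cmp0$barrier_z - cmp0$barrier_cv), 1e-9)
})

test_that("sampled FES error against quadrature decreases with run length", {
  spec <- doubleWellSpec(barrier = 4, deltaG = -2)
  sys <- buildSystem(spec, seed = 1)
  g <- seq(-1.8, 1.8, length.out = 37)
  oracle <- freeEnergy(analyticFes(spec, "x", g, 310))
  err <- vapply(c(1e4, 16e4), function(n) {
    tr <- runLangevin(sys, nSteps = n, dt = 0.05, temperature = 310,
                      seed = 12, stride = 5L)
    f <- freeEnergy(fesNd(tr@frames[, 1, 1], grid = g, temperature = 310,
                          nBoot = 0))
    occ <- !is.na(f) & oracle < 8
    sqrt(mean((f[occ] - oracle[occ])^2))
  }, 1)
  expect_lt(err[2], err[1] + 0.05)

  ## FES serialization round trip
  tr <- runLangevin(sys, nSteps = 5e3, dt = 0.05, temperature = 310,
                    seed = 3, stride = 5L)
  f <- fesNd(tr@frames[, 1, 1], grid = g, temperature = 310, nBoot = 8)
  p <- withr::local_tempfile(fileext = ".dat")
  writeFes(f, p)
  back <- readColvar(p)
  ok <- !is.na(as.numeric(freeEnergy(f)))
  expect_equal(back$free_energy[ok], as.numeric(freeEnergy(f))[ok],
               tolerance = 1e-6)
})
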