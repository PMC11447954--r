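test_that("potential specs enforce their invariants", {
  expect_error(doubleWellSpec(barrier = -1), "barrier")
  expect_error(miniBilayerSpec(soluteBeads = 1), "bead count")
  expect_error(miniBilayerSpec(slabHalfWidth = 7), "box z-length")
  expect_error(miniBilayerSpec(pairRange = 3), "pair-well range")
  expect_s4_class(insertionSpec(coupling = 0.5), "PotentialSpec")
})

test_that("system construction is deterministic and dimensioned", {
  expect_equal(nDof(buildSystem(doubleWellSpec(), 3)), 1)
  s1 <- buildSystem(miniBilayerSpec(), seed = 7)
  s2 <- buildSystem(miniBilayerSpec(), seed = 7)
  expect_identical(coordinates(s1), coordinates(s2))
  s3 <- buildSystem(miniBilayerSpec(), seed = 8)
  expect_false(identical(coordinates(s1), coordinates(s3)))
  ## symmetric slab about z = 0, solute in water
  zm <- coordinates(s1)[s1@membraneIdx, 3]
  expect_lt(abs(mean(zm)), 1e-9)
  expect_true(all(coordinates(s1)[s1@soluteIdx, 3] > 1.5))
})

test_that("forces are the exact negative analytic gradient", {
  set.seed(42)
  dw <- buildSystem(doubleWellSpec(barrier = 12, deltaG = -8), 1)
  ## stationary points at the two minima of the untilted well
  sym <- buildSystem(doubleWellSpec(barrier = 10, deltaG = 0), 1)
  expect_equal(energyForce(sym, matrix(1))$forces[1], 0, tolerance = 1e-12)
  expect_equal(energyForce(sym, matrix(-1))$forces[1], 0, tolerance = 1e-12)
  for (i in 1:40)
    expect_lt(numGradErr(dw, matrix(runif(1, -2.5, 2.5), 1, 1)), 1e-4)
  ins <- buildSystem(insertionSpec(barrier = 9, deltaG = -5, coupling = 0.7), 1)
  for (i in 1:30)
    expect_lt(numGradErr(ins, matrix(runif(2, -2, 2), 1, 2)), 1e-4)
  mb <- buildSystem(miniBilayerSpec(), 1)
  for (i in 1:3) {
    x <- coordinates(mb) + matrix(rnorm(nDof(mb), sd = 0.05),
                                  nrow(coordinates(mb)), 3)
    expect_lt(numGradErr(x = x, sys = mb), 1e-4)
  }
  ## periodicity: translating by one box vector leaves the energy unchanged
  x <- coordinates(mb)
  xs <- x; xs[, 1] <- xs[, 1] + mb@box[1]
  expect_equal(energyForce(mb, x)$energy, energyForce(mb, xs)$energy,
               tolerance = 1e-10)
  expect_error(energyForce(mb, x * NA), "non-finite")
  expect_error(energyForce(mb, x[-1, ]), "shape mismatch")
})

test_that("BAOAB Langevin obeys equipartition, determinism and stability checks", {
  k <- 8
  sys <- buildSystem(harmonicSpec(k = k), 1)
  tr <- runLangevin(sys, nSteps = 6e4, dt = 0.02, temperature = 310,
                    seed = 2, stride = 5L)
  x <- tr@frames[, 1, 1]
  ## block SE accounting for autocorrelation
  bl <- split(x^2, cut(seq_along(x), 24))
  se <- sd(vapply(bl, mean, 1)) / sqrt(24)
  expect_lt(abs(mean(x^2) - kBoltz * 310 / k), 3 * se)

  ## weak accuracy: halving dt moves <x^2> by less than its SE
  tr2 <- runLangevin(sys, nSteps = 12e4, dt = 0.01, temperature = 310,
                     seed = 2, stride = 10L)
  expect_lt(abs(mean(tr2@frames[, 1, 1]^2) - mean(x^2)), 3 * se)

  ## zero temperature at a stationary point: no motion at all
  dwsys <- buildSystem(doubleWellSpec(), 1)
  tr0 <- runLangevin(dwsys, nSteps = 500, dt = 0.02, temperature = 0,
                     seed = 3, stride = 10L)
  expect_lt(max(abs(tr0@frames[, 1, 1] - 1)), 1e-10)

  ## identical (spec, seed, steps) -> identical trajectories
  a <- runLangevin(dwsys, 2000, dt = 0.05, temperature = 310, seed = 5)
  b <- runLangevin(dwsys, 2000, dt = 0.05, temperature = 310, seed = 5)
  expect_identical(a@frames, b@frames)

  ## dt stability guard
  expect_error(runLangevin(buildSystem(harmonicSpec(k = 5000), 1),
                           100, dt = 0.1, temperature = 310),
               "unstable")
})

test_that("unbiased sampling reproduces the quadrature free energy", {
  spec <- doubleWellSpec(barrier = 5, deltaG = -3)
  sys <- buildSystem(spec, 1)
  tr <- runLangevin(sys, nSteps = 2e5, dt = 0.05, temperature = 310,
                    seed = 4, stride = 10L)
  x <- tr@frames[, 1, 1]
  g <- seq(-2, 2, length.out = 41)
  fes <- fesNd(x, grid = g, temperature = 310, nBoot = 64)
  oracle <- analyticFes(spec, "x", g, 310)
  occ <- !is.na(freeEnergy(fes)) & freeEnergy(oracle) < 12
  diff <- freeEnergy(fes)[occ] - freeEnergy(oracle)[occ]
  diff <- diff - mean(diff)    # common shift is gauge
  expect_true(all(abs(diff) < 3 * pmax(uncertainty(fes)[occ], 0.05)))
  ## occupancy ratio against the Boltzmann ratio from quadrature
  b <- basinAnalysis(oracle, c(0.1, 2), c(-2, -0.1))
  ratio <- mean(x < 0) / mean(x > 0)
  expect_lt(abs(log(ratio) - (-deltaG(b) / (kBoltz * 310))), 0.15)
})

test_that("analytic FES oracle: symmetry, programmed depth, temperature scaling", {
  g <- seq(-2.2, 2.2, length.out = 221)
  sym <- analyticFes(doubleWellSpec(barrier = 10), "x", g, 310)
  expect_lt(abs(deltaG(basinAnalysis(sym, c(0.1, 2.2), c(-2.2, -0.1)))), 0.02)

  ins <- analyticFes(insertionSpec(barrier = 10, deltaG = -10, coupling = 0.2),
                     "s", g, 310)
  b <- basinAnalysis(ins, c(0.1, 2.2), c(-2.2, -0.1))
  expect_lt(abs(deltaG(b) - (-10)), 0.2)

  ## barrier measured in kBT halves when T doubles and U is fixed
  spec <- doubleWellSpec(barrier = 10)
  f1 <- analyticFes(spec, "x", g, 300)
  f2 <- analyticFes(spec, "x", g, 600)
  bar <- function(f, Tt) {
    bb <- basinAnalysis(f, c(0.1, 2.2), c(-2.2, -0.1))
    barrierHeight(bb) / (kBoltz * Tt)
  }
  expect_equal(bar(f1, 300) / bar(f2, 600), 2, tolerance = 0.02)

  expect_error(analyticFes(miniBilayerSpec(), "x", g, 310), "analytic")
})

test_that("synthetic binding curves follow the saturation model exactly at zero noise", {
  d <- generateBindingData(F0 = 100, A = 80, KD = 0.05, noiseSd = 0,
                           nReplicates = 1, seed = 1)
  expect_equal(d$fluor_pct[d$conc_mg_ml == 0], 100)
  d2 <- generateBindingData(F0 = 100, A = 80, KD = 0.05, noiseSd = 0,
                            concentrations = c(0, 0.05, 0.5, 5, 500),
                            nReplicates = 1, seed = 1)
  expect_equal(d2$fluor_pct[d2$conc_mg_ml == 0.05], 100 + 40)
  expect_lt(abs(d2$fluor_pct[d2$conc_mg_ml == 500] - 180), 0.01 * 80)
  expect_error(generateBindingData(KD = -1), "KD")
  expect_error(generateBindingData(concentrations = c(0.1, 0.2, 0.3, 0.4)),
               "include 0")
  expect_error(generateBindingData(concentrations = c(0, 0.1)), "4 distinct")
})
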