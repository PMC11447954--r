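kBT310 <- kBoltz * 310

test_that("OPES MetaD bias: initial contract, unimodal shape, strict bound", {
  st <- newOpesState(barrier = 60, temperature = 310, sigma0 = 0.1)
  b <- opesBias(st, c(-1, 0, 2), kBT310)
  expect_equal(b$bias, c(0, 0, 0))
  expect_equal(b$dbias, c(0, 0, 0))

  st1 <- opesUpdate(st, 0.3, 0, kBT310)
  g <- seq(-2, 2, length.out = 400)
  b1 <- opesBias(st1, g, kBT310)
  expect_equal(g[which.max(b1$bias)], 0.3, tolerance = 0.02)
  expect_equal(opesBias(st1, 0.3, kBT310)$dbias, 0, tolerance = 1e-8)
  ## sup - inf <= the barrier parameter, by construction
  expect_lte(max(b1$bias) - min(b1$bias), 60 + 1e-9)

  ## gamma -> 1: the well-tempered factor degeneracy gives zero bias
  stg <- newOpesState(barrier = 60, temperature = 310, sigma0 = 0.1,
                      gamma = 1)
  stg <- opesUpdate(stg, 0.0, 0, kBT310)
  expect_equal(opesBias(stg, g, kBT310)$bias, rep(0, length(g)))

  ## analytic bias gradient vs central differences
  st2 <- st1
  for (s in c(-0.5, 0.2, 0.8)) st2 <- opesUpdate(st2, s,
                                                 opesBias(st2, s, kBT310)$bias,
                                                 kBT310)
  for (s in c(-0.7, 0.05, 0.61)) {
    h <- 1e-6
    num <- (opesBias(st2, s + h, kBT310)$bias -
              opesBias(st2, s - h, kBT310)$bias) / (2 * h)
    expect_equal(opesBias(st2, s, kBT310)$dbias, num, tolerance = 1e-5)
  }
})

test_that("kernel deposition: merging conserves density, bandwidth floored and nonincreasing", {
  st <- newOpesState(barrier = 40, temperature = 310, sigma0 = 0.2,
                     sigmaMin = 0.028)
  sig <- numeric()
  for (i in 1:50) {
    V <- opesBias(st, 0.5, kBT310)$bias
    st <- opesUpdate(st, 0.5, V, kBT310)
    sig <- c(sig, st@lastSigma)
  }
  ## repeated deposition at one point compresses into few kernels
  expect_lte(nrow(kernels(st)), 3)
  ## the kernel density stays normalized (integral of the mixture = 1)
  g <- seq(-2, 3, length.out = 2001)
  dens <- memfes:::.opesDensity(st, g)$p
  expect_equal(sum(dens) * diff(g[1:2]), 1, tolerance = 1e-6)
  ## bandwidth sequence nonincreasing, floored
  expect_true(all(diff(sig) <= 1e-12))
  expect_true(all(sig >= 0.028 - 1e-12))
  stLong <- st
  for (i in 1:400) stLong <- opesUpdate(stLong, rnorm(1, 0.5, 0.05),
                                        0, kBT310)
  expect_gte(min(kernels(stLong)[, "sigma"]), 0.028 - 1e-12)
  expect_error(opesUpdate(st, NaN, 0, kBT310), "non-finite")
})

test_that("an OPES run recovers the double-well FES within 1 kJ/mol", {
  run <- opesDoubleWellRun()
  tr <- run$traj
  x <- tr@frames[, 1, 1]
  ## many round trips despite the 12 kJ/mol barrier
  expect_gt(sum(diff(sign(x)) != 0), 100)
  w <- frameWeights(tr)
  g <- seq(-1.7, 1.7, length.out = 69)
  fes <- fesNd(x, w, g, temperature = 310)
  oracle <- analyticFes(run$spec, "x", g, 310)
  Fs <- as.numeric(freeEnergy(fes)); Fo <- as.numeric(freeEnergy(oracle))
  occ <- !is.na(Fs) & !is.na(Fo) & as.numeric(fes@ess) >= 10
  expect_gt(mean(occ), 0.8)
  expect_lt(max(abs(Fs[occ] - Fo[occ])), 1)

  ## reweighting exactness: KS distance between the weighted empirical CDF
  ## and the Boltzmann CDF
  qs <- seq(-1.7, 1.7, length.out = 200)
  pw <- exp(-memfes:::.potentialOnPoints(run$spec, matrix(qs)) / kBT310)
  cdfB <- cumsum(pw) / sum(pw)
  cdfE <- vapply(qs, function(q) sum(w[x <= q]) / sum(w), 1)
  expect_lt(max(abs(cdfE - cdfB)), 0.05)

  ## boundedness on a dense grid for the final (and an intermediate) state
  b <- opesBias(run$state, seq(-3, 3, length.out = 2000), kBT310)$bias
  expect_lte(max(b) - min(b), 60 + 1e-9)
})

test_that("expanded multithermal bias: degenerate grid, shift estimator, reweighting", {
  ## single grid point at the simulation temperature -> zero bias always
  st0 <- newExpandedState(tempRange = c(310, 310), nGrid = 1L,
                          temperature = 310)
  expect_equal(expandedBias(st0, c(-5, 0, 17))$bias, c(0, 0, 0))
  expect_error(expandedBias(st0, NaN), "non-finite")

  ## constant energy stream: c_j = +(beta_j - beta) U exactly, bias 0
  st <- newExpandedState(tempRange = c(270, 500), nGrid = 8L,
                         temperature = 310)
  st <- expandedUpdate(st, rep(3, 20))
  expect_equal(st@cj, (st@betas - st@beta) * 3, tolerance = 1e-12)
  expect_equal(expandedBias(st, 3)$bias, 0, tolerance = 1e-10)

  ## two-level energy toy: c_j from the closed-form partition ratio
  u <- c(rep(1, 30), rep(4, 10))
  st2 <- newExpandedState(tempRange = c(270, 500), nGrid = 8L,
                          temperature = 310)
  st2 <- expandedUpdate(st2, u)
  db <- st2@betas - st2@beta
  closed <- -log(0.75 * exp(-db * 1) + 0.25 * exp(-db * 4))
  expect_equal(st2@cj, closed, tolerance = 1e-10)

  ## harmonic oscillator multithermal run reweights to every grid T
  k <- 8
  sys <- buildSystem(harmonicSpec(k = k), 1)
  stm <- newExpandedState(tempRange = c(270, 500), nGrid = 16L,
                          temperature = 310, stride = 100L)
  eng <- expandedEngine(stm, sys, temperature = 310)
  tr <- runLangevin(sys, nSteps = 1.5e5, dt = 0.02, temperature = 310,
                    seed = 21, bias = eng, stride = 10L)
  x <- tr@frames[, 1, 1]
  for (Tt in 1 / (kBoltz * eng$state()@betas[c(1, 6, 11, 16)])) {
    w <- frameWeights(tr, targetTemperature = Tt)
    m2 <- sum(w * x^2) / sum(w)
    bl <- split(seq_along(x), cut(seq_along(x), 20))
    ms <- vapply(bl, function(i) sum(w[i] * x[i]^2) / sum(w[i]), 1)
    se <- sd(ms) / sqrt(length(ms))
    expect_lt(abs(m2 - kBoltz * Tt / k), 3 * se)
  }
  ## multithermal consistency: reweighted to the simulation temperature it
  ## matches an unbiased run there
  w310 <- frameWeights(tr, targetTemperature = 310)
  trU <- runLangevin(sys, nSteps = 5e4, dt = 0.02, temperature = 310,
                     seed = 77, stride = 10L)
  xu <- trU@frames[, 1, 1]
  seU <- sd(xu^2) / sqrt(length(xu) / 10)
  expect_lt(abs(sum(w310 * x^2) / sum(w310) - mean(xu^2)), 3 * seU)
})

test_that("shared-bias walkers: degeneracy, pooling determinism, crossing gains", {
  spec <- doubleWellSpec(barrier = 10, deltaG = -4)
  sys <- buildSystem(spec, seed = 1)
  cv <- function(x) list(value = x[1, 1], grad = matrix(1, 1, 1))
  mkEngine <- function() opesEngine(newOpesState(barrier = 50,
                                                 temperature = 310,
                                                 sigma0 = 0.15,
                                                 stride = 200L),
                                    cv, temperature = 310)
  ## one walker == the single-walker engine, same seed
  e1 <- mkEngine()
  shared <- runSharedBias(sys, e1, nWalkers = 1L, steps = 4000,
                          seeds = 5L, dt = 0.05, temperature = 310,
                          stride = 10L)
  e2 <- mkEngine()
  single <- runLangevin(sys, nSteps = 4000, dt = 0.05, temperature = 310,
                        seed = 5L, bias = e2, stride = 10L)
  expect_equal(shared$trajectories[[1]]@frames, single@frames,
               tolerance = 1e-12)
  expect_equal(shared$trajectories[[1]]@bias, single@bias,
               tolerance = 1e-10)
  expect_equal(kernels(shared$state), kernels(e2$state()),
               tolerance = 1e-12)

  ## deterministic pooling: re-running gives an identical shared state
  e3 <- mkEngine()
  shared2 <- runSharedBias(sys, e3, nWalkers = 3L, steps = 4000,
                           seeds = c(5L, 6L, 7L), dt = 0.05,
                           temperature = 310, stride = 10L)
  e4 <- mkEngine()
  shared3 <- runSharedBias(sys, e4, nWalkers = 3L, steps = 4000,
                           seeds = c(5L, 6L, 7L), dt = 0.05,
                           temperature = 310, stride = 10L)
  expect_identical(kernels(shared2$state), kernels(shared3$state))
  expect_equal(length(shared2$trajectories), 3L)

  ## walker ensembles harvest at least as many basin crossings as one
  ## walker at equal per-walker steps (median over seeds)
  crossings <- function(trajs) sum(vapply(trajs, function(t)
    sum(diff(sign(t@frames[, 1, 1])) != 0), 1))
  gains <- vapply(1:3, function(rep) {
    eM <- mkEngine()
    multi <- runSharedBias(sys, eM, nWalkers = 4L, steps = 3000,
                           seeds = rep * 10L + 1:4, dt = 0.05,
                           temperature = 310, stride = 10L)
    eS <- mkEngine()
    one <- runSharedBias(sys, eS, nWalkers = 1L, steps = 3000,
                         seeds = rep * 10L + 1L, dt = 0.05,
                         temperature = 310, stride = 10L)
    crossings(multi$trajectories) - crossings(one$trajectories)
  }, 1)
  expect_gte(median(gains), 0)
})
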