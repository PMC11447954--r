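## Session-level fixture cache: expensive runs (biased trajectories, trained
## CVs) are computed once and shared across test files.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

## Central finite-difference force check against the analytic gradient.
numGradErr <- function(sys, x, h = 1e-5) {
  ef <- energyForce(sys, x)
  num <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    num[i] <- -(energyForce(sys, xp)$energy -
                  energyForce(sys, xm)$energy) / (2 * h)
  }
  max(abs(num - ef$forces))
}

## Slow-hopping double well used by the CV-learning tests: ~6 kBT barrier at
## 310 K gives residence times of tens of ps, i.e. a genuinely slow mode.
slowDoubleWellRun <- function() {
  fixture("slowDwRun", {
    sys <- buildSystem(doubleWellSpec(barrier = 15), seed = 1)
    runLangevin(sys, nSteps = 3e5, dt = 0.05, temperature = 310,
                seed = 101, stride = 10L)
  })
}

## OPES MetaD double-well run shared by the opes/fes/acceptance tests.
opesDoubleWellRun <- function() {
  fixture("opesDwRun", {
    spec <- doubleWellSpec(barrier = 12, deltaG = -6)
    sys <- buildSystem(spec, seed = 1)
    cv <- function(x) list(value = x[1, 1], grad = matrix(1, 1, 1))
    sigma0 <- estimateSigma0(sys, cv, nSteps = 2000, dt = 0.05,
                             temperature = 310, seed = 9)
    st <- newOpesState(barrier = 60, temperature = 310, sigma0 = sigma0,
                       stride = 500L)
    eng <- opesEngine(st, cv, temperature = 310)
    tr <- runLangevin(sys, nSteps = 3.5e5, dt = 0.05, temperature = 310,
                      seed = 11, bias = eng, stride = 10L)
    list(spec = spec, traj = tr, state = eng$state())
  })
}

## Full insertion-toy protocol at desk scale: multithermal exploration,
## Deep-TICA training on (x, y), OPES MetaD along the learned CV with 8
## shared-bias walkers, FES along both projections. Shared by the
## deep-tica, fes and acceptance tests.
insertionAccFlow <- function() {
  fixture("insAcc", {
    spec <- insertionSpec(barrier = 8, deltaG = -6, coupling = 0.8,
                          kOrth = 20)
    sys <- buildSystem(spec, seed = 1)
    st <- newExpandedState(tempRange = c(270, 500), nGrid = 24L,
                           temperature = 310, stride = 200L)
    eng <- expandedEngine(st, sys, temperature = 310)
    tr1 <- runLangevin(sys, nSteps = 1.2e5, dt = 0.05, temperature = 310,
                       seed = 31, bias = eng, stride = 10L)
    xy <- tr1@frames[, 1, ]
    colnames(xy) <- c("x", "y")
    w1 <- frameWeights(tr1)
    model <- trainDeepTica(xy, trainConfig(lag = 0.001, maxEpochs = 150,
                                           seed = 4),
                           weights = w1, zref = xy[, 1])
    cvfun <- memfes:::.cvCallable(model, sys)
    sigma0 <- estimateSigma0(sys, cvfun, nSteps = 2000, dt = 0.05,
                             temperature = 310, seed = 7)
    st2 <- newOpesState(barrier = 60, temperature = 310,
                        sigma0 = max(sigma0, 0.028), stride = 500L)
    eng2 <- opesEngine(st2, cvfun, temperature = 310)
    run2 <- runSharedBias(sys, eng2, nWalkers = 8L, steps = 3e4,
                          seeds = 41:48, dt = 0.05, temperature = 310,
                          stride = 10L)
    list(spec = spec, sys = sys, explore = tr1, xy = xy, w1 = w1,
         model = model, run2 = run2)
  })
}

## Small mini-bilayer exploration + descriptors + trained CV, shared by the
## descriptor / deep-tica / pipeline tests.
miniBilayerTrained <- function() {
  fixture("mbTrained", {
    spec <- miniBilayerSpec()
    sys <- buildSystem(spec, seed = 1)
    st <- newExpandedState(tempRange = c(270, 500), nGrid = 16L,
                           temperature = 310, stride = 200L)
    eng <- expandedEngine(st, sys, temperature = 310)
    run <- runSharedBias(sys, eng, nWalkers = 2L, steps = 10000,
                         seeds = c(11L, 12L), dt = 0.02, temperature = 310,
                         stride = 20L)
    desc <- bindDescriptors(lapply(run$trajectories, buildDescriptorMatrix,
                                   groups = NULL, discard = 20))
    model <- trainDeepTica(desc, trainConfig(lag = 0.005, maxEpochs = 60,
                                             seed = 5))
    list(spec = spec, sys = sys, run = run, desc = desc, model = model)
  })
}
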