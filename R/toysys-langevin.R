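#' BAOAB Langevin dynamics on a toy system
#'
#' NVT Langevin dynamics with the BAOAB splitting (best configurational
#' accuracy per step among the common Langevin splittings). An optional bias
#' adds forces on top of the physical potential and its energy is recorded
#' per frame. The run is reproducible from `seed`.
#'
#' `bias` may be (a) `NULL`, (b) a plain function `f(coords)` returning
#' `list(energy, forces)` for a static bias, or (c) a stateful bias engine
#' created by [opesEngine()] / [expandedEngine()], in which case kernel
#' deposition / shift updates happen every `engine stride` steps.
#'
#' @param system a [ToySystem-class]
#' @param nSteps number of integrator steps
#' @param dt time step (ps); validated against the stiffest well of the
#'   system, stop otherwise
#' @param temperature thermostat temperature (K)
#' @param friction Langevin friction (1/ps)
#' @param seed integer RNG seed
#' @param bias optional bias (see Details)
#' @param stride record every `stride` steps
#' @param x0,v0 optional initial coordinates / velocities (defaults:
#'   `coordinates(system)` and a Maxwell draw)
#' @param walker walker index recorded in the trajectory
#' @return a [Trajectory-class]
#' @examples
#' sys <- buildSystem(doubleWellSpec(barrier = 5), seed = 1)
#' tr <- runLangevin(sys, nSteps = 2000, dt = 0.05, temperature = 310, seed = 7)
#' @export
runLangevin <- function(system, nSteps, dt = 0.02, temperature = 310,
                        friction = 1.0, seed = 1L, bias = NULL, stride = 10L,
                        x0 = NULL, v0 = NULL, walker = 1L) {
  kmax <- .stiffness(system@spec)
  omega <- sqrt(kmax / min(system@masses))
  if (dt * omega > 1)
    stop(sprintf("dt = %g ps unstable for stiffest curvature %.3g kJ/mol/nm^2 (need dt < %.3g)",
                 dt, kmax, 1 / omega))
  engine <- inherits(bias, "memfesBiasEngine")
  biasFun <- if (engine) bias$evaluate else bias
  depStride <- if (engine) bias$stride else NA_integer_

  x <- if (is.null(x0)) system@coords0 else as.matrix(x0)
  n <- nrow(x); d <- ncol(x)
  m <- system@masses
  kBT <- .kBT(temperature)
  c1 <- exp(-friction * dt)
  c2 <- sqrt((1 - c1^2) * kBT / m)   # per-particle noise amplitude

  nFrames <- nSteps %/% stride
  frames <- array(NA_real_, c(nFrames, n, d))
  pot <- bias_e <- cvrec <- rep(NA_real_, nFrames)

  withSeed(seed, {
    v <- if (is.null(v0)) {
      matrix(stats::rnorm(n * d, sd = sqrt(kBT / m)), n, d)
    } else as.matrix(v0)
    ef <- energyForce(system, x)
    bf <- if (is.null(biasFun)) NULL else biasFun(x)
    Ftot <- ef$forces + if (is.null(bf)) 0 else bf$forces
    frame <- 0L
    for (step in seq_len(nSteps)) {
      v <- v + (dt / 2) * Ftot / m
      x <- x + (dt / 2) * v
      v <- c1 * v + c2 * matrix(stats::rnorm(n * d), n, d)
      x <- x + (dt / 2) * v
      ef <- energyForce(system, x)
      if (!is.finite(ef$energy) || abs(ef$energy) > 1e6)
        stop("energy divergence at step ", step, " (U = ", ef$energy, ")")
      bf <- if (is.null(biasFun)) NULL else biasFun(x)
      Ftot <- ef$forces + if (is.null(bf)) 0 else bf$forces
      v <- v + (dt / 2) * Ftot / m
      if (step %% stride == 0L) {
        frame <- frame + 1L
        xr <- x
        for (ax in which(system@periodic))
          xr[, ax] <- xr[, ax] %% system@box[ax]
        frames[frame, , ] <- xr
        pot[frame] <- ef$energy
        bias_e[frame] <- if (is.null(bf)) 0 else bf$energy
        cvrec[frame] <- if (engine && !is.null(bias$cvValue)) bias$cvValue(x) else NA_real_
      }
      if (engine && step %% depStride == 0L) {
        bias$deposit(x, ef$energy)
        bf <- biasFun(x)                      # bias changed: refresh forces
        Ftot <- ef$forces + bf$forces
      }
    }
  })
  new("Trajectory", frames = frames, times = seq_len(nFrames) * stride * dt,
      potential = pot, bias = bias_e, cv = cvrec,
      temperature = temperature, system = system,
      seed = as.integer(seed), walker = as.integer(walker))
}

## Final phase-space state of a chunked run; used by the shared-bias driver.
#' @noRd
.langevinChunk <- function(system, x, v, nSteps, dt, temperature, friction,
                           biasFun, rngState = NULL) {
  ## Low-level: advances (x, v) without recording; caller manages RNG.
  m <- system@masses
  kBT <- .kBT(temperature)
  c1 <- exp(-friction * dt)
  c2 <- sqrt((1 - c1^2) * kBT / m)
  n <- nrow(x); d <- ncol(x)
  ef <- energyForce(system, x)
  bf <- if (is.null(biasFun)) NULL else biasFun(x)
  Ftot <- ef$forces + if (is.null(bf)) 0 else bf$forces
  for (step in seq_len(nSteps)) {
    v <- v + (dt / 2) * Ftot / m
    x <- x + (dt / 2) * v
    v <- c1 * v + c2 * matrix(stats::rnorm(n * d), n, d)
    x <- x + (dt / 2) * v
    ef <- energyForce(system, x)
    if (!is.finite(ef$energy) || abs(ef$energy) > 1e6)
      stop("energy divergence (U = ", ef$energy, ")")
    bf <- if (is.null(biasFun)) NULL else biasFun(x)
    Ftot <- ef$forces + if (is.null(bf)) 0 else bf$forces
    v <- v + (dt / 2) * Ftot / m
  }
  list(x = x, v = v, potential = ef$energy,
       biasEnergy = if (is.null(bf)) 0 else bf$energy)
}
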