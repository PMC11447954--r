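#' Unbiased bandwidth estimate for OPES
#'
#' Short unbiased pre-run returning the CV standard deviation, the
#' standard choice for the initial adaptive kernel bandwidth.
#'
#' @param system a [ToySystem-class]
#' @param cv function(coords) -> `list(value, grad)` (or plain value)
#' @param nSteps,dt,temperature,friction,seed pre-run settings
#' @return standard deviation of the CV (CV units)
#' @export
estimateSigma0 <- function(system, cv, nSteps = 2000, dt = 0.02,
                           temperature = 310, friction = 1, seed = 99L) {
  tr <- runLangevin(system, nSteps, dt = dt, temperature = temperature,
                    friction = friction, seed = seed, stride = 5L)
  vals <- apply(tr@frames, 1, function(fr) {
    v <- cv(matrix(fr, dim(tr@frames)[2], dim(tr@frames)[3]))
    if (is.list(v)) v$value else v
  })
  stats::sd(vals)
}

#' Multi-walker shared-bias sampling
#'
#' Runs `nWalkers` independent Langevin replicas that share a single bias:
#' walkers propagate independently between deposition strides; at each
#' stride every walker contributes its sample to the common state in a
#' deterministic order (walker index, then time), after which all walkers
#' evaluate the identical updated bias. A diverging walker is aborted and
#' logged; the run continues with the remaining walkers.
#'
#' @param system a [ToySystem-class]
#' @param engine a shared bias engine ([opesEngine()] / [expandedEngine()])
#' @param nWalkers number of replicas (reference protocol: 8)
#' @param steps integrator steps per walker
#' @param seeds one seed per walker
#' @param dt,temperature,friction integrator settings
#' @param stride recording stride (must divide the deposition stride)
#' @param x0 optional initial coordinates (shared by all walkers)
#' @return list with `trajectories` (one [Trajectory-class] per surviving
#'   walker), `state` (final shared bias state), and `events` (log)
#' @export
runSharedBias <- function(system, engine, nWalkers = 8L, steps,
                          seeds = NULL, dt = 0.02, temperature = 310,
                          friction = 1, stride = 10L, x0 = NULL) {
  stopifnot(inherits(engine, "memfesBiasEngine"))
  dep <- engine$stride
  if (dep %% stride != 0L)
    stop("recording stride must divide the deposition stride")
  if (is.null(seeds)) seeds <- seq_len(nWalkers)
  stopifnot(length(seeds) == nWalkers)
  nCycles <- steps %/% dep
  subPerCycle <- dep %/% stride
  kBT <- .kBT(temperature)

  x0 <- if (is.null(x0)) system@coords0 else as.matrix(x0)
  n <- nrow(x0); d <- ncol(x0)
  walkers <- lapply(seq_len(nWalkers), function(w) {
    withSeed(seeds[w], {
      v <- matrix(stats::rnorm(n * d, sd = sqrt(kBT / system@masses)), n, d)
      list(x = x0, v = v, rng = get(".Random.seed", envir = globalenv()),
           frames = array(NA_real_, c(nCycles * subPerCycle, n, d)),
           pot = numeric(0), bias = numeric(0), cv = numeric(0),
           frame = 0L, active = TRUE)
    })
  })
  events <- character()

  oldSeed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))

  for (cyc in seq_len(nCycles)) {
    samples <- vector("list", nWalkers)
    for (w in seq_len(nWalkers)) {
      wk <- walkers[[w]]
      if (!wk$active) next
      assign(".Random.seed", wk$rng, envir = globalenv())
      ok <- TRUE
      for (sub in seq_len(subPerCycle)) {
        res <- tryCatch(
          .langevinChunk(system, wk$x, wk$v, stride, dt, temperature,
                         friction, engine$evaluate),
          error = function(e) e)
        if (inherits(res, "error")) {
          events <- c(events, sprintf("walker %d aborted in cycle %d: %s",
                                      w, cyc, conditionMessage(res)))
          wk$active <- FALSE
          ok <- FALSE
          break
        }
        wk$x <- res$x; wk$v <- res$v
        wk$frame <- wk$frame + 1L
        xr <- wk$x
        for (ax in which(system@periodic))
          xr[, ax] <- xr[, ax] %% system@box[ax]
        wk$frames[wk$frame, , ] <- xr
        wk$pot <- c(wk$pot, res$potential)
        wk$bias <- c(wk$bias, res$biasEnergy)
        wk$cv <- c(wk$cv, if (!is.null(engine$cvValue))
          engine$cvValue(wk$x) else NA_real_)
      }
      wk$rng <- get(".Random.seed", envir = globalenv())
      walkers[[w]] <- wk
      if (ok)
        samples[[w]] <- list(x = wk$x, potential = wk$pot[length(wk$pot)])
    }
    ## deterministic pooling: walker index order, then time
    for (w in seq_len(nWalkers)) {
      if (!is.null(samples[[w]]))
        engine$deposit(samples[[w]]$x, samples[[w]]$potential)
    }
  }

  trajs <- list()
  for (w in seq_len(nWalkers)) {
    wk <- walkers[[w]]
    if (wk$frame == 0L) next
    trajs[[length(trajs) + 1L]] <- new("Trajectory",
      frames = wk$frames[seq_len(wk$frame), , , drop = FALSE],
      times = seq_len(wk$frame) * stride * dt,
      potential = wk$pot, bias = wk$bias, cv = wk$cv,
      temperature = temperature, system = system,
      seed = as.integer(seeds[w]), walker = w)
  }
  list(trajectories = trajs, state = engine$state(), events = events)
}
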