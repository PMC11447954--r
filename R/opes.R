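#' Create an OPES MetaD bias state
#'
#' On-the-fly probability enhanced sampling toward the well-tempered
#' target along one CV: Gaussian kernels rebuild the marginal probability
#' of the CV, and the bias is derived from that density estimate rather
#' than accumulated directly. With the default couplings
#' gamma = barrier/kBT and eps = exp(-barrier/((1 - 1/gamma) kBT)), the
#' bias range is confined to [-barrier, 0] (the "maximum barrier that can
#' be overcome" parameter, default 60 kJ/mol).
#'
#' @param barrier maximum crossable barrier Delta-E (kJ/mol)
#' @param temperature simulation temperature (K), fixes kBT and defaults
#' @param sigma0 initial kernel bandwidth (CV units); usually the unbiased
#'   CV standard deviation from a short pre-run
#' @param sigmaMin bandwidth floor (CV units, default 0.028)
#' @param gamma bias factor; default barrier/kBT
#' @param stride deposition stride in integrator steps (default 500)
#' @param mergeThreshold kernel-merge distance in units of the existing
#'   kernel's bandwidth
#' @return an [OpesState-class] with an empty kernel list (bias identically
#'   zero until the first deposition)
#' @export
newOpesState <- function(barrier = 60, temperature = 310, sigma0 = NA_real_,
                         sigmaMin = 0.028, gamma = NULL, stride = 500L,
                         mergeThreshold = 1.0) {
  kBT <- .kBT(temperature)
  if (is.null(gamma)) gamma <- barrier / kBT
  ## gamma <= 1 degenerates to the unbiased target (zero bias); eps unused
  eps <- if (gamma <= 1) 1 else exp(-barrier / ((1 - 1 / gamma) * kBT))
  new("OpesState",
      kernels = matrix(numeric(), 0, 3,
                       dimnames = list(NULL, c("center", "sigma", "height"))),
      gamma = gamma, eps = eps, barrier = barrier, sigma0 = sigma0,
      sigmaMin = sigmaMin, stride = as.integer(stride),
      mergeThreshold = mergeThreshold, pmax = 0, Z = 1, sumW = 0, sumW2 = 0,
      lastSigma = Inf, nDeposits = 0L)
}

## Kernel density estimate at points s (normalized Gaussian mixture with
## height weights); returns density and its derivative.
#' @noRd
.opesDensity <- function(state, s) {
  K <- state@kernels
  if (!nrow(K)) return(list(p = rep(0, length(s)), dp = rep(0, length(s))))
  hsum <- sum(K[, "height"])
  p <- dp <- numeric(length(s))
  for (q in seq_along(s)) {
    z <- (s[q] - K[, "center"]) / K[, "sigma"]
    g <- K[, "height"] * exp(-z^2 / 2) / (K[, "sigma"] * sqrt(2 * pi))
    p[q] <- sum(g) / hsum
    dp[q] <- sum(-g * z / K[, "sigma"]) / hsum
  }
  list(p = p, dp = dp)
}

#' Evaluate the OPES MetaD bias
#'
#' V(s) = (1 - 1/gamma) kBT log(eps + (1 - eps) min(p(s)/pmax, 1)), where
#' p is the running kernel density estimate and pmax its maximum over the
#' kernel centers. Before the first deposition the bias and its gradient
#' are identically zero; afterwards the bias is smooth, nonpositive, and
#' bounded below by -barrier.
#'
#' @param state an [OpesState-class]
#' @param s CV value(s)
#' @param kBT thermal energy (kJ/mol)
#' @return list with `bias` and `dbias` (same length as `s`)
#' @export
opesBias <- function(state, s, kBT) {
  ## gamma -> 1 is the zero-bias (unbiased target) degeneracy
  if (!nrow(state@kernels) || state@pmax <= 0 || state@gamma <= 1)
    return(list(bias = rep(0, length(s)), dbias = rep(0, length(s))))
  den <- .opesDensity(state, s)
  q <- den$p / state@pmax
  dq <- den$dp / state@pmax
  pref <- (1 - 1 / state@gamma) * kBT
  clip <- q >= 1
  q[clip] <- 1
  dq[clip] <- 0
  arg <- state@eps + (1 - state@eps) * q
  list(bias = pref * log(arg), dbias = pref * (1 - state@eps) * dq / arg)
}

#' Deposit a kernel into an OPES MetaD state
#'
#' Appends a Gaussian kernel at the current CV value with weight
#' exp(V/kBT) (the well-tempered reweighting of the deposition point). The
#' bandwidth shrinks with the effective sample size as
#' sigma0 * n_eff^(-1/5), is forced nonincreasing, and never drops below
#' the floor. Kernels closer than `mergeThreshold` bandwidths are merged
#' moment-preservingly; the running normalization Z (mean density over
#' kernel centers) and pmax (max density over centers) are refreshed.
#'
#' @param state an [OpesState-class]
#' @param s CV value at the deposition step
#' @param V current bias at `s` (kJ/mol), i.e. `opesBias(state, s, kBT)`
#' @param kBT thermal energy (kJ/mol)
#' @return the updated [OpesState-class]
#' @export
opesUpdate <- function(state, s, V, kBT) {
  if (!is.finite(s)) stop("non-finite CV value at deposition")
  if (!is.finite(state@sigma0))
    stop("sigma0 unset: provide the unbiased CV standard deviation")
  h <- exp(V / kBT)
  state@sumW <- state@sumW + h
  state@sumW2 <- state@sumW2 + h^2
  neff <- state@sumW^2 / state@sumW2
  sig <- max(state@sigmaMin, state@sigma0 * neff^(-1 / 5))
  sig <- min(sig, state@lastSigma)
  state@lastSigma <- sig
  K <- state@kernels
  merged <- FALSE
  if (nrow(K)) {
    dist <- abs(K[, "center"] - s)
    nn <- which.min(dist)
    if (dist[nn] < state@mergeThreshold * K[nn, "sigma"]) {
      ## moment-preserving merge of (center, sigma, height) pairs
      h0 <- K[nn, "height"]; m0 <- K[nn, "center"]; s0 <- K[nn, "sigma"]
      ht <- h0 + h
      mt <- (h0 * m0 + h * s) / ht
      st <- sqrt((h0 * (s0^2 + m0^2) + h * (sig^2 + s^2)) / ht - mt^2)
      K[nn, ] <- c(mt, max(st, state@sigmaMin), ht)
      merged <- TRUE
    }
  }
  if (!merged) K <- rbind(K, c(s, sig, h))
  state@kernels <- K
  state@nDeposits <- state@nDeposits + 1L
  den <- .opesDensity(state, K[, "center"])
  state@pmax <- max(den$p)
  state@Z <- mean(den$p)
  state
}

#' Create an OPES expanded (multithermal) bias state
#'
#' Targets the multithermal distribution over an inverse-temperature grid
#' so a single run samples a whole temperature range (default 270-500 K,
#' 64 geometrically spaced beta points, simulated at 310 K). The bias acts
#' on the potential energy:
#' V(U) = -kBT log[(1/N) sum_j exp(-(beta_j - beta) U + c_j)], with the
#' shifts c_j estimated self-consistently from the sampled energies.
#'
#' @param tempRange explored temperature range (K)
#' @param nGrid number of beta grid points
#' @param temperature simulation temperature (K), inside `tempRange`
#' @param stride update stride in integrator steps
#' @return an [ExpandedState-class] with zero-initialized shifts
#' @export
newExpandedState <- function(tempRange = c(270, 500), nGrid = 64L,
                             temperature = 310, stride = 500L) {
  bmax <- 1 / .kBT(min(tempRange))
  bmin <- 1 / .kBT(max(tempRange))
  betas <- sort(exp(seq(log(bmin), log(bmax), length.out = nGrid)))
  new("ExpandedState", betas = betas, beta = 1 / .kBT(temperature),
      cj = numeric(nGrid), logSumW = -Inf, logTerms = rep(-Inf, nGrid),
      stride = as.integer(stride), nSamples = 0L)
}

#' Evaluate the multithermal expanded bias
#'
#' Overflow-guarded log-sum-exp over the beta grid. With a single grid
#' point at the simulation temperature the bias is identically zero.
#'
#' @param state an [ExpandedState-class]
#' @param U potential energy value(s) (kJ/mol)
#' @return list with `bias` and `dbias` (derivative w.r.t. U)
#' @export
expandedBias <- function(state, U) {
  if (any(!is.finite(U))) stop("non-finite potential energy")
  dbeta <- state@betas - state@beta
  kBT <- 1 / state@beta
  out <- vapply(U, function(u) {
    ex <- -dbeta * u + state@cj
    m <- max(ex)
    se <- sum(exp(ex - m))
    lse <- m + log(se / length(ex))
    dV <- sum(dbeta * exp(ex - m)) / se   # weighted mean of dbeta
    c(-kBT * lse, kBT * dV)
  }, numeric(2))
  list(bias = out[1, ], dbias = out[2, ])
}

#' Update the expanded-ensemble shifts from new energy samples
#'
#' c_j is minus the running log-mean-exp of -(beta_j - beta) U over the
#' sampled energies, corrected for the current bias via weights
#' exp(beta V): at convergence each grid term contributes order one to the
#' bias. Deterministic given sample order.
#'
#' @param state an [ExpandedState-class]
#' @param U new potential-energy samples
#' @param V bias values at those samples (0 before any bias exists)
#' @return the updated [ExpandedState-class]
#' @export
expandedUpdate <- function(state, U, V = 0) {
  stopifnot(length(U) >= 1)
  V <- rep_len(V, length(U))
  logw <- state@beta * V
  dbeta <- state@betas - state@beta
  for (k in seq_along(U)) {
    state@logSumW <- logSumExp(c(state@logSumW, logw[k]))
    state@logTerms <- vapply(seq_along(dbeta), function(j)
      logSumExp(c(state@logTerms[j], logw[k] - dbeta[j] * U[k])), numeric(1))
  }
  state@nSamples <- state@nSamples + length(U)
  state@cj <- -(state@logTerms - state@logSumW)
  validObject(state)
  state
}

## ---------------------------------------------------------------------------
## Stateful engine wrappers used inside the integrator. Environments give
## the reference semantics needed for shared-bias walkers; the functional
## state objects above remain the checkpoint/value API.

#' Bias engines for Langevin runs
#'
#' `opesEngine` biases a scalar CV of the coordinates (value + gradient via
#' `cv`), depositing kernels every `state stride` steps. `expandedEngine`
#' biases the potential energy itself toward the multithermal target.
#' Engines are mutable environments; `engine$state()` returns the current
#' functional state object.
#'
#' @param state an [OpesState-class] or [ExpandedState-class]
#' @param cv function(coords) returning `list(value, grad)` with `grad`
#'   shaped like the coordinates
#' @param system the [ToySystem-class] being biased (expanded engine needs
#'   it to recompute energies)
#' @param temperature simulation temperature (K)
#' @return an engine usable as the `bias` argument of [runLangevin()]
#' @export
opesEngine <- function(state, cv, temperature = 310) {
  kBT <- .kBT(temperature)
  env <- new.env(parent = emptyenv())
  env$st <- state
  eng <- list(
    stride = state@stride,
    evaluate = function(x) {
      c1 <- cv(x)
      b <- opesBias(env$st, c1$value, kBT)
      list(energy = b$bias, forces = -b$dbias * c1$grad)
    },
    deposit = function(x, potential) {
      s <- cv(x)$value
      V <- opesBias(env$st, s, kBT)$bias
      env$st <- opesUpdate(env$st, s, V, kBT)
    },
    cvValue = function(x) cv(x)$value,
    state = function() env$st,
    setState = function(s) env$st <- s)
  class(eng) <- "memfesBiasEngine"
  eng
}

#' @rdname opesEngine
#' @export
expandedEngine <- function(state, system, temperature = 310) {
  env <- new.env(parent = emptyenv())
  env$st <- state
  env$buf <- numeric()
  eng <- list(
    stride = state@stride,
    evaluate = function(x) {
      ef <- energyForce(system, x)
      b <- expandedBias(env$st, ef$energy)
      ## bias force = -dV/dU * dU/dx = +dV/dU * F_physical
      list(energy = b$bias, forces = b$dbias * ef$forces)
    },
    deposit = function(x, potential) {
      V <- expandedBias(env$st, potential)$bias
      env$st <- expandedUpdate(env$st, potential, V)
    },
    cvValue = function(x) energyForce(system, x)$energy,
    state = function() env$st,
    setState = function(s) env$st <- s)
  class(eng) <- "memfesBiasEngine"
  eng
}
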