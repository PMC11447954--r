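#' Reweighting frame weights from the recorded bias
#'
#' w ∝ exp(V/kBT), normalized to mean 1; constant bias shifts cancel. For
#' multithermal (expanded) records an optional target temperature adds the
#' potential-energy reweighting factor exp((beta - beta_target) U),
#' turning one multithermal run into an estimator at any grid temperature.
#'
#' @param traj a [Trajectory-class] (or a list with `bias`, `potential`,
#'   `temperature` entries)
#' @param targetTemperature optional reweighting temperature (K)
#' @return numeric weights, mean 1
#' @export
frameWeights <- function(traj, targetTemperature = NULL) {
  V <- if (is(traj, "Trajectory")) traj@bias else traj$bias
  U <- if (is(traj, "Trajectory")) traj@potential else traj$potential
  Tsim <- if (is(traj, "Trajectory")) traj@temperature else traj$temperature
  if (is.null(V)) stop("no bias record in trajectory")
  lw <- V / .kBT(Tsim)
  if (!is.null(targetTemperature)) {
    if (is.null(U)) stop("potential-energy record required for temperature reweighting")
    lw <- lw + (1 / .kBT(Tsim) - 1 / .kBT(targetTemperature)) * U
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  w / mean(w)
}

#' Reweighted free-energy surface along one or two CVs
#'
#' F = -kBT log of the weighted (optionally Gaussian-smoothed) histogram,
#' min-shifted to zero. Per-bin standard errors come from a block
#' bootstrap, with walkers as blocks when block labels are given and 8
#' contiguous time blocks otherwise. Never-visited bins are `NA`, not
#' zero.
#'
#' @param cv numeric vector (1D) or T x 2 matrix (2D) of CV values
#' @param weights per-frame weights (e.g. [frameWeights()]); default 1
#' @param grid list of axis bin centers, or a single numeric vector for 1D
#' @param temperature temperature (K)
#' @param bw smoothing bandwidth per axis in CV units; `0` = raw
#'   histogram. Default: 0 in 1D, the bin width in 2D
#' @param blocks optional per-frame block labels (walker ids)
#' @param nBoot bootstrap replicates
#' @param seed bootstrap seed
#' @param cvNames axis names
#' @return a [FreeEnergySurface-class]; bootstrap replicate surfaces are
#'   kept in `metadata$bootF` for downstream error propagation
#' @export
fesNd <- function(cv, weights = NULL, grid, temperature = 310, bw = NULL,
                  blocks = NULL, nBoot = 64L, seed = 7L,
                  cvNames = NULL) {
  kBT <- .kBT(temperature)
  X <- if (is.null(dim(cv))) matrix(cv, ncol = 1) else as.matrix(cv)
  nd <- ncol(X)
  if (is.numeric(grid) && nd == 1) grid <- list(grid)
  stopifnot(length(grid) == nd)
  T <- nrow(X)
  w <- if (is.null(weights)) rep(1, T) else weights
  stopifnot(length(w) == T)
  if (is.null(bw)) bw <- if (nd == 1) 0 else vapply(grid, function(g) diff(g[1:2]), 1)
  bw <- rep_len(bw, nd)
  if (is.null(cvNames)) cvNames <- paste0("cv", seq_len(nd))
  if (is.null(blocks)) blocks <- cut(seq_len(T), breaks = min(8, T), labels = FALSE)

  idx <- matrix(0L, T, nd)
  nb <- vapply(grid, length, 1L)
  for (ax in seq_len(nd)) {
    g <- grid[[ax]]
    h <- diff(g[1:2])
    breaks <- c(g - h / 2, g[nb[ax]] + h / 2)
    idx[, ax] <- findInterval(X[, ax], breaks, rightmost.closed = TRUE)
  }
  inside <- rowSums(idx >= 1 & sweep(idx, 2, nb, "<=")) == nd
  if (!sum(inside)) stop("no samples fall inside the grid")
  flat <- idx[inside, 1]
  if (nd == 2) flat <- flat + (idx[inside, 2] - 1L) * nb[1]
  ws <- w[inside]

  accumulate <- function(wvec) {
    mass <- numeric(prod(nb))
    tb <- tapply(wvec, flat, sum)
    mass[as.integer(names(tb))] <- tb
    if (nd == 1) {
      if (bw[1] > 0) mass <- .gaussSmooth1(mass, bw[1] / diff(grid[[1]][1:2]))
    } else {
      mass <- matrix(mass, nb[1], nb[2])
      for (ax in 1:2) {
        s <- bw[ax] / diff(grid[[ax]][1:2])
        if (s > 0) mass <- if (ax == 1) apply(mass, 2, .gaussSmooth1, s = s)
                   else t(apply(mass, 1, .gaussSmooth1, s = s))
      }
      mass <- as.numeric(mass)
    }
    mass
  }
  toF <- function(mass) ifelse(mass > 0, -kBT * log(mass), NA_real_)

  mass <- accumulate(ws)
  if (sum(mass > 0) == 1) warning("all weight mass in a single bin")
  F <- toF(mass)
  F <- F - min(F, na.rm = TRUE)

  ## per-bin effective sample size
  w2 <- numeric(prod(nb))
  tb <- tapply(ws^2, flat, sum)
  w2[as.integer(names(tb))] <- tb
  m1 <- numeric(prod(nb))
  tb <- tapply(ws, flat, sum)
  m1[as.integer(names(tb))] <- tb
  ess <- ifelse(w2 > 0, m1^2 / w2, 0)

  blk <- blocks[inside]
  ublk <- unique(blk)
  bootF <- NULL
  se <- rep(NA_real_, prod(nb))
  if (length(ublk) >= 2 && nBoot > 0) {
    bootF <- withSeed(seed, {
      lapply(seq_len(nBoot), function(r) {
        pick <- sample(ublk, length(ublk), replace = TRUE)
        mult <- numeric(length(ws))
        for (b in pick) mult[blk == b] <- mult[blk == b] + 1
        m <- accumulate(ws * mult)
        toF(m)
      })
    })
    BM <- do.call(cbind, bootF)
    ## center each replicate on its own occupied-bin mean (shifts are gauge)
    BM <- sweep(BM, 2, colMeans(BM, na.rm = TRUE))
    se <- apply(BM, 1, stats::sd, na.rm = TRUE)
    se[is.na(F)] <- NA_real_
  }
  shape <- if (nd == 1) nb[1] else nb
  new("FreeEnergySurface", grid = grid,
      values = array(F, shape), se = array(se, shape),
      ess = array(ess, shape), cvNames = cvNames,
      cvUnits = rep("nm", nd), temperature = temperature,
      metadata = list(bootF = bootF, nBoot = nBoot,
                      blocks = length(ublk)))
}

## discrete Gaussian smoothing of a histogram (s in bins)
#' @noRd
.gaussSmooth1 <- function(mass, s) {
  n <- length(mass)
  half <- max(1L, ceiling(4 * s))
  k <- stats::dnorm(seq(-half, half), sd = s)
  k <- k / sum(k)
  out <- numeric(n)
  for (off in seq(-half, half)) {
    src <- seq_len(n) - off
    ok <- src >= 1 & src <= n
    out[ok] <- out[ok] + k[off + half + 1] * mass[src[ok]]
  }
  out
}

#' Basin free-energy difference and entry barrier from a 1D FES
#'
#' The basin free-energy difference uses bin-integrated Boltzmann weights,
#' dG = -kBT log(sum_B exp(-F/kBT) / sum_A exp(-F/kBT)) (the
#' thermodynamically meaningful definition; reduces to the minima
#' difference for sharp basins — `method = "minima"` gives that variant).
#' The entry barrier is F at the highest point between the two basin
#' minima minus F at the basin-A minimum. Uncertainties are propagated
#' from the block-bootstrap replicate surfaces.
#'
#' @param fes a 1D [FreeEnergySurface-class]
#' @param rangeA,rangeB disjoint CV ranges `c(lo, hi)` defining the basins
#'   (A is conventionally the starting/water basin)
#' @param method `"integral"` (default) or `"minima"`
#' @return a [BasinResult-class]
#' @export
basinAnalysis <- function(fes, rangeA, rangeB, method = c("integral", "minima")) {
  method <- match.arg(method)
  stopifnot(length(fes@grid) == 1)
  g <- fes@grid[[1]]
  kBT <- .kBT(fes@temperature)
  if (max(rangeA[1], rangeB[1]) < min(rangeA[2], rangeB[2]))
    stop("basin ranges must be disjoint")
  inA <- g >= rangeA[1] & g <= rangeA[2]
  inB <- g >= rangeB[1] & g <= rangeB[2]
  F <- as.numeric(fes@values)
  if (!any(inA & !is.na(F)) || !any(inB & !is.na(F)))
    stop("each basin range must contain at least one occupied bin")
  dGof <- function(F) {
    if (method == "integral") {
      -kBT * (logSumExp(-F[inB & !is.na(F)] / kBT) -
                logSumExp(-F[inA & !is.na(F)] / kBT))
    } else {
      min(F[inB], na.rm = TRUE) - min(F[inA], na.rm = TRUE)
    }
  }
  dG <- dGof(F)
  iA <- which(inA)[which.min(F[inA])]
  iB <- which(inB)[which.min(F[inB])]
  path <- seq(min(iA, iB), max(iA, iB))
  iS <- path[which.max(F[path])]
  flags <- character()
  barrier <- F[iS] - F[iA]
  if (iS %in% c(iA, iB) || barrier <= 0) {
    barrier <- 0
    flags <- c(flags, "monotone")
  }
  se <- 0
  if (!is.null(fes@metadata$bootF)) {
    reps <- vapply(fes@metadata$bootF, function(Fb) {
      if (!any(inA & !is.na(Fb)) || !any(inB & !is.na(Fb))) return(NA_real_)
      dGof(Fb)
    }, numeric(1))
    se <- stats::sd(reps, na.rm = TRUE)
  }
  new("BasinResult", dG = dG, dGse = se, barrier = barrier,
      barrierLocation = g[iS], minima = c(g[iA], g[iB]),
      ranges = list(A = rangeA, B = rangeB), flags = flags, method = method)
}

#' Compare free-energy estimates along two CV projections
#'
#' The basin free-energy difference is path independent, so the estimates
#' along the physical z-projection and along a learned CV must agree
#' within their combined standard error; the barrier, in contrast, is
#' projection dependent and a poor CV (transition region overlapping the
#' basins) underestimates it.
#'
#' @param fesZ,fesCv 1D surfaces from the same trajectory set
#' @param rangesZ,rangesCv lists with elements `A` and `B` giving the
#'   basin ranges on each projection
#' @return list report: dG and barrier per projection, combined SE, and
#'   agreement indicator (|dG difference| <= 2 * combined SE)
#' @export
compareCvFes <- function(fesZ, fesCv, rangesZ, rangesCv) {
  bz <- basinAnalysis(fesZ, rangesZ$A, rangesZ$B)
  bc <- basinAnalysis(fesCv, rangesCv$A, rangesCv$B)
  comb <- sqrt(bz@dGse^2 + bc@dGse^2)
  list(dG_z = bz@dG, se_z = bz@dGse,
       dG_cv = bc@dG, se_cv = bc@dGse,
       combinedSE = comb,
       dG_difference = abs(bz@dG - bc@dG),
       dG_agree = abs(bz@dG - bc@dG) <= 2 * max(comb, 1e-12),
       barrier_z = bz@barrier, barrier_cv = bc@barrier,
       basins = list(z = bz, cv = bc))
}

#' Write a FES as a COLVAR-dialect grid table / CSV
#'
#' @param fes a [FreeEnergySurface-class]
#' @param path output path
#' @param format `"colvar"` or `"csv"`
#' @export
writeFes <- function(fes, path, format = c("colvar", "csv")) {
  format <- match.arg(format)
  if (length(fes@grid) == 1) {
    df <- data.frame(fes@grid[[1]], as.numeric(fes@values),
                     as.numeric(fes@se))
    colnames(df) <- c(fes@cvNames, "free_energy", "se")
  } else {
    gg <- expand.grid(fes@grid[[1]], fes@grid[[2]])
    df <- data.frame(gg, as.numeric(fes@values), as.numeric(fes@se))
    colnames(df) <- c(fes@cvNames, "free_energy", "se")
  }
  if (format == "csv") utils::write.csv(df, path, row.names = FALSE)
  else writeColvar(df, path, meta = list(temperature = fes@temperature))
  invisible(path)
}
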