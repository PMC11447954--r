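## Potential on arbitrary points for the analytic specs (rows of X are
## configurations in the spec's own dimensionality).
#' @noRd
.potentialOnPoints <- function(spec, X) {
  p <- spec@params
  switch(spec@kind,
    harmonic_1d = 0.5 * p$k * X[, 1]^2,
    double_well_1d = .dwU(X[, 1], p$barrier, p$a, p$deltaG),
    insertion_2d = .dwU(X[, 1] + p$coupling * X[, 2], p$barrier, p$a, p$deltaG) +
      0.5 * p$kOrth * X[, 2]^2,
    stop("analytic potential not available for kind '", spec@kind, "'"))
}

## Resolve a CV definition into a function over configuration rows.
#' @noRd
.cvFunction <- function(spec, cv) {
  if (is.function(cv)) return(cv)
  p <- spec@params
  switch(cv,
    x = function(X) X[, 1],
    y = function(X) X[, 2],
    s = function(X) if (spec@kind == "insertion_2d")
          X[, 1] + p$coupling * X[, 2] else X[, 1],
    stop("unknown CV definition '", cv, "'"))
}

#' Exact free-energy surface of an analytic toy by quadrature
#'
#' Computes F(s) = -kB*T*log integral delta(cv - s) exp(-U/kB*T) by
#' deterministic quadrature on a fine grid, min-shifted to zero. Serves as
#' the oracle against which sampled and reweighted surfaces are compared.
#' Only the analytic specs (`double_well_1d`, `insertion_2d`) are supported.
#'
#' @param spec an analytic [PotentialSpec-class]
#' @param cv `"x"`, `"y"`, `"s"` (slow direction) or a function mapping a
#'   matrix of configurations to CV values
#' @param grid numeric vector of uniform bin centers for the output
#' @param temperature temperature (K)
#' @param quadN quadrature nodes per axis
#' @return a [FreeEnergySurface-class] with zero uncertainty
#' @examples
#' fes <- analyticFes(doubleWellSpec(deltaG = -10), "x",
#'                    grid = seq(-2, 2, length.out = 101), temperature = 310)
#' @export
analyticFes <- function(spec, cv = "x", grid, temperature = 310,
                        quadN = NULL) {
  kBT <- .kBT(temperature)
  p <- spec@params
  dom <- p$domain
  if (spec@kind == "mini_bilayer")
    stop("analyticFes requires an analytic spec, not mini_bilayer")
  if (is.null(quadN)) quadN <- if (length(dom) == 1) 20001L else 601L
  if (length(dom) == 1) {
    xs <- seq(dom$x[1], dom$x[2], length.out = quadN)
    X <- matrix(xs, ncol = 1)
    dV <- diff(dom$x) / (quadN - 1)
  } else {
    xs <- seq(dom$x[1], dom$x[2], length.out = quadN)
    ys <- seq(dom$y[1], dom$y[2], length.out = quadN)
    X <- as.matrix(expand.grid(x = xs, y = ys))
    dV <- diff(dom$x) * diff(dom$y) / (quadN - 1)^2
  }
  U <- .potentialOnPoints(spec, X)
  lw <- -U / kBT
  mlw <- max(lw)
  if (length(dom) == 1) {
    edgeDensity <- max(exp(lw[1] - mlw), exp(lw[quadN] - mlw))
  } else {
    onEdge <- X[, 1] %in% dom$x | X[, 2] %in% dom$y
    edgeDensity <- max(exp(lw[onEdge] - mlw))
  }
  if (edgeDensity > 1e-6)
    stop("potential is unnormalizable on the stated domain ",
         "(relative boundary density ", signif(edgeDensity, 3), ")")
  s <- .cvFunction(spec, cv)(X)
  .binnedFes(s, exp(lw - mlw) * dV, grid, kBT, temperature,
             cvName = if (is.character(cv)) cv else "cv")
}

## Shared histogram -> F helper (exact weights; no smoothing, no SE).
#' @noRd
.binnedFes <- function(s, w, grid, kBT, temperature, cvName = "cv") {
  h <- diff(grid[1:2])
  breaks <- c(grid - h / 2, grid[length(grid)] + h / 2)
  idx <- findInterval(s, breaks, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= length(grid)
  mass <- vapply(seq_along(grid),
                 function(b) sum(w[keep][idx[keep] == b]), numeric(1))
  F <- ifelse(mass > 0, -kBT * log(mass), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  new("FreeEnergySurface", grid = list(grid), values = array(F, length(grid)),
      se = array(0, length(grid)), ess = array(Inf, length(grid)),
      cvNames = cvName, cvUnits = "nm", temperature = temperature,
      metadata = list(source = "quadrature"))
}

#' Synthetic fluorescence-binding titration
#'
#' Draws normalized fluorescence values from the hyperbolic saturation
#' curve F(L) = F0 + A*L/(KD + L) plus i.i.d. Gaussian noise, emulating a
#' LUV titration normalized so that the no-vesicle point is 100%.
#'
#' @param F0 fluorescence at L = 0 (%); the normalization convention fixes
#'   this at 100
#' @param A emission difference between bound and unbound states (%)
#' @param KD dissociation constant (mg/mL total lipid), > 0
#' @param concentrations LUV concentrations (mg/mL); must include 0 and at
#'   least 4 distinct values
#' @param noiseSd homoscedastic Gaussian noise (% units), >= 0
#' @param nReplicates replicates per concentration
#' @param seed RNG seed
#' @return data.frame with columns `conc_mg_ml`, `fluor_pct`, `replicate`
#'   and attribute `noise_sd`
#' @examples
#' generateBindingData(A = 120, KD = 0.013, noiseSd = 2, seed = 1)
#' @export
generateBindingData <- function(F0 = 100, A = 100, KD = 0.013,
                                concentrations = c(0, 0.01, 0.025, 0.05,
                                                   0.1, 0.2, 0.4, 0.7, 1.0),
                                noiseSd = 2, nReplicates = 5, seed = 1L) {
  stopifnot(KD > 0, noiseSd >= 0)
  if (!any(concentrations == 0) || any(concentrations < 0))
    stop("concentrations must be >= 0 and include 0")
  if (length(unique(concentrations)) < 4)
    stop("at least 4 distinct concentrations required")
  L <- rep(concentrations, times = nReplicates)
  mu <- F0 + A * L / (KD + L)
  withSeed(seed, {
    val <- mu + stats::rnorm(length(L), sd = noiseSd)
  })
  out <- data.frame(conc_mg_ml = L, fluor_pct = val,
                    replicate = rep(seq_len(nReplicates),
                                    each = length(concentrations)))
  attr(out, "noise_sd") <- noiseSd
  attr(out, "truth") <- c(F0 = F0, A = A, KD = KD)
  out
}
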