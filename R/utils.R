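#' Boltzmann constant in simulation units
#'
#' Global unit system: lengths in nm, times in ps, energies in kJ/mol,
#' temperatures in K, charges in e. `kBoltz` is the molar Boltzmann constant
#' (identical to the gas constant R) in kJ/mol/K, the GROMACS convention.
#'
#' @export
kBoltz <- 0.0083144621

#' @noRd
.kBT <- function(temperature) kBoltz * temperature

## Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
## the caller's .Random.seed afterwards. All stochastic entry points use this
## so that determinism contracts hold without clobbering user RNG state.
#' @noRd
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Counter-based seed splitter: one global seed fans out to per-stage /
## per-walker streams. Kept below 2^31 - 1.
#' @noRd
splitSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1299709) %% 2147483629) + 1L
}

#' @noRd
logSumExp <- function(x, b = NULL) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  if (is.null(b)) m + log(sum(exp(x - m))) else m + log(sum(b * exp(x - m)))
}

## Mean-normalized soft minimum: -(1/beta) log( mean exp(-beta d) ).
## Lies at or above min(d) and decreases monotonically to it as beta -> Inf.
#' @noRd
softMin <- function(d, beta) {
  -(logSumExp(-beta * d) - log(length(d))) / beta
}

## Minimum-image displacement along one axis.
#' @noRd
minImage <- function(dx, L) {
  if (!is.finite(L)) return(dx)
  dx - L * round(dx / L)
}

## Area under the ROC curve via the rank-sum statistic. `score` should be
## larger for the positive class.
#' @noRd
rocAuc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  if (!length(pos) || !length(neg)) stop("both classes required for ROC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## Tiny FNV-1a style checksum over a character scalar; used to detect
## tampered model files without a hashing dependency.
#' @noRd
textChecksum <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
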