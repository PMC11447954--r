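## Time-lagged pair selection. Without weights the lag is in frames; with
## weights the lag is measured on the rescaled-time clock (cumulative
## weight), and a lag < 1 is read as a fraction of the total rescaled
## length. Pair weight: sqrt(w_i * w_j).
#' @noRd
.lagPairs <- function(T, lag, weights = NULL, episodes = NULL) {
  pr <- .lagPairsRaw(T, lag, weights)
  if (!is.null(episodes)) {
    keep <- episodes[pr$i] == episodes[pr$j]
    if (!any(keep)) stop("no lagged pairs remain within episodes")
    pr$i <- pr$i[keep]; pr$j <- pr$j[keep]; pr$w <- pr$w[keep]
  }
  pr
}

#' @noRd
.lagPairsRaw <- function(T, lag, weights = NULL) {
  if (is.null(weights)) {
    if (lag < 1) lag <- max(1, round(lag * T))
    lag <- as.integer(round(lag))
    if (T <= lag) stop("need more frames than the lag")
    i <- seq_len(T - lag)
    list(i = i, j = i + lag, w = rep(1, length(i)), lag = lag,
         lagUnit = "frames")
  } else {
    stopifnot(length(weights) == T, all(weights >= 0))
    tres <- cumsum(weights)
    total <- tres[T]
    lagR <- if (lag < 1) lag * total else lag
    if (lagR <= 0 || lagR >= total)
      stop("rescaled lag must fall inside the rescaled trajectory length")
    j <- findInterval(tres + lagR, tres, left.open = TRUE) + 1L
    keep <- j <= T
    i <- which(keep)
    j <- j[keep]
    if (!length(i)) stop("need more frames than the lag")
    list(i = i, j = j, w = sqrt(weights[i] * weights[j]), lag = lagR,
         lagUnit = "rescaled")
  }
}

#' Weighted time-lagged covariance estimation
#'
#' Mean-free, reversible (symmetrized) estimators of the instantaneous and
#' time-lagged covariances. With per-frame weights (e.g. w = exp(V/kBT)
#' from a biased run) the lag is measured on the rescaled-time clock: frame
#' pairs are selected so that the cumulative weight between them equals the
#' requested lag, which unbiases the slow-mode estimate without discarding
#' data.
#'
#' @param X T x d matrix of time-ordered features
#' @param lag lag: in frames (`weights = NULL`) or in rescaled-time units;
#'   a `lag` < 1 with weights is interpreted as a fraction of the total
#'   rescaled trajectory length
#' @param weights optional nonnegative per-frame weights
#' @return a [LaggedCovariances-class]
#' @export
laggedCovariances <- function(X, lag, weights = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  pr <- .lagPairs(nrow(X), lag, weights)
  i <- pr$i; j <- pr$j; w <- pr$w
  lagUnit <- pr$lagUnit; lagOut <- pr$lag
  sw <- sum(w)
  A <- X[i, , drop = FALSE]
  B <- X[j, , drop = FALSE]
  mu <- as.numeric((crossprod(A, w) + crossprod(B, w)) / (2 * sw))
  A <- sweep(A, 2, mu)
  B <- sweep(B, 2, mu)
  wA <- A * w
  C0 <- (crossprod(wA, A) + crossprod(B * w, B)) / (2 * sw)
  Ct <- crossprod(wA, B) / sw
  Ct <- (Ct + t(Ct)) / 2
  ess <- sw^2 / sum(w^2)
  rankDef <- ess < d + 1
  if (rankDef)
    warning("fewer than d+1 effective pairs (", round(ess, 1),
            "); covariance is rank deficient")
  new("LaggedCovariances", C0 = C0, Ct = Ct, means = mu, lag = lagOut,
      lagUnit = lagUnit, ess = ess, nPairs = length(i),
      rankDeficient = rankDef)
}

#' Solve the TICA generalized eigenproblem
#'
#' Solves Ct v = lambda (C0 + eps_r I) v by symmetric whitening. The
#' leading eigenvectors are the linear combinations of features with
#' maximal autocorrelation at the lag (the slowest decorrelating modes, by
#' the variational principle). Eigenvalues above 1 are clipped with the
#' event logged; eigenvectors are rescaled to exact C0-orthonormality when
#' C0 permits.
#'
#' @param cov a [LaggedCovariances-class]
#' @param nModes number of modes to keep
#' @param eps ridge regularization; default `1e-6 * tr(C0)/d`, stabilizing
#'   near-duplicate minimum-distance features
#' @return a [TicaModel-class]
#' @export
solveTica <- function(cov, nModes = 2L, eps = NULL) {
  C0 <- cov@C0; Ct <- cov@Ct
  d <- ncol(C0)
  stopifnot(nModes <= d)
  if (is.null(eps)) eps <- 1e-6 * sum(diag(C0)) / d
  ev0 <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) < -1e-8 * max(abs(ev0)))
    stop("C0 is not positive semidefinite (smallest eigenvalue ",
         signif(min(ev0), 4), ")")
  R <- chol(C0 + eps * diag(d))
  Ri <- backsolve(R, diag(d))
  Mw <- t(Ri) %*% Ct %*% Ri
  Mw <- (Mw + t(Mw)) / 2
  es <- eigen(Mw, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)[seq_len(nModes)]
  lam <- es$values[ord]
  clipped <- sum(lam > 1)
  lam <- pmin(lam, 1)
  V <- Ri %*% es$vectors[, ord, drop = FALSE]
  ## exact C0-normalization where possible
  for (k in seq_len(nModes)) {
    nrm <- sqrt(drop(t(V[, k]) %*% C0 %*% V[, k]))
    if (nrm > 1e-10) V[, k] <- V[, k] / nrm
  }
  ts <- impliedTimescalesFromEvals(lam, cov@lag)
  new("TicaModel", evals = lam, evecs = V, lag = cov@lag,
      lagUnit = cov@lagUnit, timescales = ts$times, flagged = ts$flagged,
      clipped = as.integer(clipped), means = cov@means)
}

#' @noRd
impliedTimescalesFromEvals <- function(lam, lag) {
  times <- rep(NA_real_, length(lam))
  flagged <- rep(FALSE, length(lam))
  pos <- lam > 0 & lam < 1
  times[pos] <- -lag / log(lam[pos])
  times[lam >= 1] <- Inf
  flagged[lam >= 1 | lam <= 0] <- TRUE
  times[lam <= 0] <- NaN
  list(times = times, flagged = flagged)
}

#' Implied relaxation timescales of a TICA model
#'
#' t_i = -lag / log(lambda_i) for lambda in (0, 1). Unit eigenvalues map to
#' `Inf` and non-positive ones to `NaN`; both are flagged via
#' `attr(, "flagged")`, never silently dropped.
#'
#' @param model a [TicaModel-class]
#' @return numeric timescales with a `flagged` attribute
#' @export
impliedTimescales <- function(model) {
  ts <- impliedTimescalesFromEvals(model@evals, model@lag)
  structure(ts$times, flagged = ts$flagged)
}

#' Project features onto TICA modes
#'
#' @param model a [TicaModel-class]
#' @param X T x d feature matrix
#' @return T x k matrix of mode values
#' @export
ticaProject <- function(model, X) {
  sweep(as.matrix(X), 2, model@means) %*% model@evecs
}
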