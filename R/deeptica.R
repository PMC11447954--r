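#' Standardize a feature matrix
#'
#' Scales every column to zero mean and unit variance. Zero-variance
#' columns are dropped, with the column mapping logged in the returned
#' standardizer so downstream evaluation can state exactly which features
#' it expects.
#'
#' @param X T x d feature matrix (T >= 2)
#' @return list with `Xs` (standardized matrix) and `std`
#'   (means, sds, keep, dropped)
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("standardization needs at least two rows")
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  keep <- sd > 1e-12
  if (!any(keep)) stop("all columns have zero variance")
  dropped <- colnames(X)[!keep] %||% which(!keep)
  Xs <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  Xs <- sweep(Xs, 2, sd[keep], "/")
  list(Xs = Xs,
       std = list(means = mu[keep], sds = sd[keep],
                  keep = which(keep), d = ncol(X),
                  names = colnames(X)[keep], dropped = dropped))
}

#' @rdname standardize
#' @param std a standardizer from `standardize()`
#' @export
applyStandardizer <- function(X, std) {
  X <- as.matrix(X)
  if (ncol(X) == std$d) X <- X[, std$keep, drop = FALSE]
  if (ncol(X) != length(std$means))
    stop("feature dimension mismatch: expected the retained set {",
         paste(std$names, collapse = ", "), "}")
  sweep(sweep(X, 2, std$means), 2, std$sds, "/")
}

#' @rdname standardize
#' @export
invertStandardizer <- function(Xs, std) {
  sweep(sweep(as.matrix(Xs), 2, std$sds, "*"), 2, std$means, "+")
}

#' Deep-TICA training configuration
#'
#' Defaults follow the reference training protocol: two hidden tanh layers
#' of 128 and 64 nodes, Adam with learning rate 1e-3, early stopping with a
#' patience of 10 epochs, four optimized eigenvalues, and a lag of 0.01
#' interpreted as a fraction of the (rescaled) trajectory length.
#'
#' @param lag lag time; values < 1 are a fraction of the (rescaled)
#'   trajectory length
#' @param nEigen number of eigenvalues entering the loss
#' @param hidden hidden layer widths
#' @param lr Adam learning rate
#' @param patience early-stopping patience (epochs), >= 1
#' @param valFrac validation fraction (contiguous block, taken last)
#' @param maxEpochs epoch cap
#' @param seed training seed (initialization)
#' @return a list of class `trainConfig`
#' @export
trainConfig <- function(lag = 0.01, nEigen = 4L, hidden = c(128L, 64L),
                        lr = 1e-3, patience = 10L, valFrac = 0.2,
                        maxEpochs = 200L, seed = 1L) {
  stopifnot(patience >= 1, lr > 0, valFrac > 0, valFrac < 1)
  structure(list(lag = lag, nEigen = as.integer(nEigen),
                 hidden = as.integer(hidden), lr = lr,
                 patience = as.integer(patience), valFrac = valFrac,
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed)),
            class = "trainConfig")
}

## --- minimal dense tanh network -------------------------------------------

#' @noRd
.mlpInit <- function(arch, seed) {
  withSeed(seed, {
    W <- list()
    for (l in seq_len(length(arch) - 1)) {
      fanIn <- arch[l]; fanOut <- arch[l + 1]
      lim <- sqrt(6 / (fanIn + fanOut))
      W[[paste0("W", l)]] <- matrix(stats::runif(fanIn * fanOut, -lim, lim),
                                    fanIn, fanOut)
      W[[paste0("b", l)]] <- numeric(fanOut)
    }
    W
  })
}

## forward pass; hidden layers tanh, output linear
#' @noRd
.mlpForward <- function(W, X) {
  nl <- length(W) / 2
  H <- list(X)
  for (l in seq_len(nl)) {
    Z <- H[[l]] %*% W[[paste0("W", l)]]
    Z <- sweep(Z, 2, W[[paste0("b", l)]], "+")
    H[[l + 1]] <- if (l < nl) tanh(Z) else Z
  }
  H
}

## backward pass: dY is the loss gradient at the output; returns parameter
## gradients and (optionally) the gradient with respect to the input rows.
#' @noRd
.mlpBackward <- function(W, H, dY, inputGrad = FALSE) {
  nl <- length(W) / 2
  g <- list()
  delta <- dY
  for (l in rev(seq_len(nl))) {
    g[[paste0("W", l)]] <- crossprod(H[[l]], delta)
    g[[paste0("b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(W[[paste0("W", l)]])) * (1 - H[[l]]^2)
    } else if (inputGrad) {
      delta <- delta %*% t(W[[paste0("W", 1)]])
    }
  }
  list(grads = g, dX = if (inputGrad) delta else NULL)
}

## TICA loss -sum(lambda^2) on network outputs plus its gradient with
## respect to the two pair legs A = Y[i,], B = Y[j,].
## dlambda = v' dCt v - lambda v' dC0 v with v normalized v'(C0+eps)v = 1.
#' @noRd
.ticaLossGrad <- function(A, B, w, nEigen, eps = 1e-6) {
  sw <- sum(w)
  mu <- as.numeric((crossprod(A, w) + crossprod(B, w)) / (2 * sw))
  Ac <- sweep(A, 2, mu); Bc <- sweep(B, 2, mu)
  wAc <- Ac * w; wBc <- Bc * w
  C0 <- (crossprod(wAc, Ac) + crossprod(wBc, Bc)) / (2 * sw)
  Ct <- (crossprod(wAc, Bc) + crossprod(wBc, Ac)) / (2 * sw)
  K <- ncol(A)
  ridge <- eps * max(sum(diag(C0)) / K, 1e-12)
  R <- tryCatch(chol(C0 + ridge * diag(K)), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Ri <- backsolve(R, diag(K))
  Mw <- t(Ri) %*% Ct %*% Ri
  Mw <- (Mw + t(Mw)) / 2
  es <- eigen(Mw, symmetric = TRUE)
  k <- min(nEigen, K)
  ord <- order(es$values, decreasing = TRUE)[seq_len(k)]
  lam <- es$values[ord]
  V <- Ri %*% es$vectors[, ord, drop = FALSE]   # v'(C0+ridge)v = 1
  loss <- -sum(lam^2)
  Gt <- V %*% diag(-2 * lam, k) %*% t(V)
  G0 <- V %*% diag(2 * lam^2, k) %*% t(V)
  dAc <- (wBc %*% Gt + wAc %*% G0) / sw
  dBc <- (wAc %*% Gt + wBc %*% G0) / sw
  S <- colSums(dAc + dBc)
  dA <- dAc - (w / (2 * sw)) %o% S
  dB <- dBc - (w / (2 * sw)) %o% S
  list(loss = loss, evals = lam, dA = dA, dB = dB, mu = mu, V = V, C0 = C0)
}

#' Train a Deep-TICA collective variable
#'
#' Optimizes a feed-forward tanh network so that the leading TICA
#' eigenvalues of its outputs are maximal at the configured lag: the loss
#' is -sum of the squared top `nEigen` eigenvalues of the time-lagged
#' generalized eigenproblem solved on the network outputs. Training is
#' full-batch with Adam, early-stopped on the validation loss of a
#' contiguous 80/20 time-block split (validation last), and deterministic
#' given the seed. Biased input is handled through rescaled-time pairing
#' using the per-frame log-weights.
#'
#' The returned model's CV (leading TICA combination of the outputs) is
#' affinely scaled so the training-set range maps onto [-1, 1], with the
#' sign fixed so the frame of maximal z-distance (the water state) maps
#' toward +1.
#'
#' @param desc a [DescriptorSet-class], or a plain T x d matrix
#' @param cfg a [trainConfig()]
#' @param weights optional per-frame weights; defaults to
#'   `exp(logweight)` from `desc`
#' @param zref optional reference series for the sign convention (defaults
#'   to the z-distance auxiliary column)
#' @param episodes optional per-frame trajectory ids; lagged pairs never
#'   cross an episode boundary (defaults to the walker column)
#' @return a [DeepTicaModel-class]
#' @export
trainDeepTica <- function(desc, cfg = trainConfig(), weights = NULL,
                          zref = NULL, episodes = NULL) {
  if (is(desc, "DescriptorSet")) {
    X <- desc@values
    if (is.null(weights)) {
      lw <- desc@aux$logweight
      if (!all(lw == 0)) weights <- exp(lw - max(lw))
    }
    if (is.null(zref)) zref <- desc@aux$z_dist
    if (is.null(episodes) && !is.null(desc@aux$walker))
      episodes <- desc@aux$walker
  } else X <- as.matrix(desc)
  T <- nrow(X)
  sres <- standardize(X)
  Xs <- sres$Xs
  std <- sres$std
  if (length(std$dropped))
    message("dropped ", length(std$dropped), " zero-variance column(s): ",
            paste(std$dropped, collapse = ", "))
  nTrain <- floor((1 - cfg$valFrac) * T)
  idxT <- seq_len(nTrain)
  idxV <- (nTrain + 1L):T
  wT <- weights[idxT]; wV <- weights[idxV]
  prT <- .lagPairs(length(idxT), cfg$lag, wT, episodes[idxT])
  prV <- .lagPairs(length(idxV), cfg$lag, wV, episodes[idxV])
  XT <- Xs[idxT, , drop = FALSE]
  XV <- Xs[idxV, , drop = FALSE]

  arch <- as.integer(c(ncol(Xs), cfg$hidden, cfg$nEigen))
  W <- .mlpInit(arch, cfg$seed)
  adamM <- lapply(W, function(x) x * 0)
  adamV <- lapply(W, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; adamEps <- 1e-8

  valLoss <- function(W) {
    H <- .mlpForward(W, XV)
    Y <- H[[length(H)]]
    r <- .ticaLossGrad(Y[prV$i, , drop = FALSE], Y[prV$j, , drop = FALSE],
                       prV$w, cfg$nEigen)
    if (is.null(r)) Inf else r$loss
  }

  log <- data.frame(epoch = integer(), train = numeric(), valid = numeric(),
                    lambda1 = numeric())
  best <- list(loss = valLoss(W), W = W, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(cfg$maxEpochs)) {
    H <- .mlpForward(W, XT)
    Y <- H[[length(H)]]
    r <- .ticaLossGrad(Y[prT$i, , drop = FALSE], Y[prT$j, , drop = FALSE],
                       prT$w, cfg$nEigen)
    if (is.null(r) || !is.finite(r$loss))
      stop("divergent loss at epoch ", epoch)
    dY <- matrix(0, nrow(Y), ncol(Y))
    ## scatter-add pair gradients back onto frames
    for (col in seq_len(ncol(Y))) {
      dY[, col] <- dY[, col] +
        unname(tapply(c(r$dA[, col], r$dB[, col]), c(prT$i, prT$j), sum)[
          as.character(seq_len(nrow(Y)))])
    }
    dY[is.na(dY)] <- 0
    bk <- .mlpBackward(W, H, dY)
    t <- epoch
    for (nm in names(W)) {
      g <- bk$grads[[nm]]
      adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g
      adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g^2
      mhat <- adamM[[nm]] / (1 - b1^t)
      vhat <- adamV[[nm]] / (1 - b2^t)
      W[[nm]] <- W[[nm]] - cfg$lr * mhat / (sqrt(vhat) + adamEps)
    }
    vl <- valLoss(W)
    log <- rbind(log, data.frame(epoch = epoch, train = r$loss, valid = vl,
                                 lambda1 = r$evals[1]))
    if (vl < best$loss - 1e-10) {
      best <- list(loss = vl, W = W, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (best$epoch == 0L)
    warning("validation loss never improved; returning the epoch-0 model")
  W <- best$W

  ## final TICA on the training outputs of the selected model
  H <- .mlpForward(W, XT)
  Y <- H[[length(H)]]
  r <- .ticaLossGrad(Y[prT$i, , drop = FALSE], Y[prT$j, , drop = FALSE],
                     prT$w, cfg$nEigen)
  proj <- r$V[, 1]
  std$outMeans <- r$mu
  raw <- as.numeric(sweep(.mlpForward(W, Xs)[[length(arch)]], 2, r$mu) %*% proj)
  if (!is.null(zref)) {
    ## water (maximal z-distance decile) must map toward +1
    hi <- zref >= stats::quantile(zref, 0.9)
    lo <- zref <= stats::quantile(zref, 0.1)
    if (mean(raw[hi]) < mean(raw[lo])) proj <- -proj
  }
  raw <- as.numeric(sweep(.mlpForward(W, Xs)[[length(arch)]], 2, r$mu) %*% proj)
  a <- 2 / (max(raw) - min(raw))
  b <- -1 - a * min(raw)
  new("DeepTicaModel", std = std, weights = W, arch = arch, proj = proj,
      scaleA = a, scaleB = b, evals = r$evals, lag = prT$lag,
      lagUnit = prT$lagUnit, featureNames = std$names %||% character(),
      trainLog = log, seed = cfg$seed)
}

#' Evaluate a Deep-TICA CV (and its gradient)
#'
#' Applies the standardizer, the network, the TICA projection and the
#' affine scaling. The affine map sends the training-set CV range onto
#' [-1, 1] (water toward +1); out-of-range inputs may exceed [-1, 1] and
#' are deliberately not clipped.
#'
#' @param model a [DeepTicaModel-class]
#' @param x descriptor vector, or a T x d matrix of frames
#' @param gradient also return d(cv)/d(descriptors) (original units)
#' @return numeric CV values; with `gradient = TRUE` a list
#'   `(value, grad)` for a single input row
#' @export
evaluateCv <- function(model, x, gradient = FALSE) {
  X <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (!is.null(colnames(X)) && length(model@featureNames) &&
      ncol(X) == length(model@featureNames))
    colnames(X) <- NULL
  Xs <- applyStandardizer(X, model@std)
  H <- .mlpForward(model@weights, Xs)
  Y <- H[[length(H)]]
  raw <- as.numeric(sweep(Y, 2, model@std$outMeans) %*% model@proj)
  val <- model@scaleA * raw + model@scaleB
  if (!gradient) return(val)
  if (nrow(X) != 1) stop("gradient evaluation expects a single frame")
  dY <- matrix(model@proj * model@scaleA, 1, length(model@proj))
  bk <- .mlpBackward(model@weights, H, dY, inputGrad = TRUE)
  grad <- as.numeric(bk$dX) / model@std$sds
  names(grad) <- model@featureNames
  list(value = val, grad = grad)
}

#' Number of trainable parameters of a Deep-TICA model
#' @param model a [DeepTicaModel-class]
#' @export
nParameters <- function(model) {
  sum(vapply(model@weights, length, 1L))
}

#' Export / load a Deep-TICA model
#'
#' Writes the full model (standardizer, weights, projection, scaling, sign
#' rule and training log) to a self-describing JSON file at full floating
#' point precision, with a checksum over the numeric payload. `loadModel`
#' refuses files with a wrong format version or a failing checksum.
#'
#' @param model a [DeepTicaModel-class]
#' @param path file path
#' @export
exportModel <- function(model, path) {
  payload <- list(
    format = "memfes-deeptica", version = 1L,
    arch = model@arch, featureNames = model@featureNames,
    std = model@std, weights = lapply(model@weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))
    }),
    proj = model@proj, scaleA = model@scaleA, scaleB = model@scaleB,
    evals = model@evals, lag = model@lag, lagUnit = model@lagUnit,
    seed = model@seed, trainLog = model@trainLog)
  num <- jsonlite::toJSON(payload$weights, digits = NA, auto_unbox = TRUE)
  payload$checksum <- textChecksum(as.character(num))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname exportModel
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "memfes-deeptica") || !identical(p$version, 1L))
    stop("unrecognized model file version: ",
         p$format %||% "?", " v", p$version %||% "?")
  W <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  num <- jsonlite::toJSON(lapply(W, function(w) {
    if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
    else list(dim = length(w), data = as.numeric(w))
  }), digits = NA, auto_unbox = TRUE)
  if (!identical(textChecksum(as.character(num)), p$checksum))
    stop("model file checksum mismatch (tampered or truncated file)")
  std <- p$std
  std$keep <- as.integer(std$keep)
  new("DeepTicaModel", std = std, weights = W, arch = as.integer(p$arch),
      proj = as.numeric(p$proj), scaleA = p$scaleA, scaleB = p$scaleB,
      evals = as.numeric(p$evals), lag = p$lag, lagUnit = p$lagUnit,
      featureNames = as.character(p$featureNames %||% character()),
      trainLog = as.data.frame(p$trainLog), seed = as.integer(p$seed))
}
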