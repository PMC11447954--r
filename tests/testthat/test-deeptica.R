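test_that("standardization contracts: dropping, round trip, split transfer", {
  set.seed(3)
  X <- cbind(a = rnorm(500, 5, 2), b = rep(1.5, 500), c = runif(500))
  s <- standardize(X)
  expect_equal(s$std$dropped, "b")
  expect_equal(colMeans(s$Xs), c(a = 0, c = 0), tolerance = 1e-12)
  expect_equal(apply(s$Xs, 2, sd), c(a = 1, c = 1), tolerance = 1e-12)
  back <- invertStandardizer(s$Xs, s$std)
  expect_equal(unname(back), unname(X[, c(1, 3)]), tolerance = 1e-10)
  ## standardizer from one half applied to the other: means near 0
  XA <- X[1:250, ]; XB <- X[251:500, ]
  sA <- standardize(XA)
  zb <- applyStandardizer(XB, sA$std)
  expect_true(all(abs(colMeans(zb)) < 3 / sqrt(250)))
  expect_error(standardize(matrix(1, 10, 2)), "zero variance")
  expect_error(applyStandardizer(X[, 1:2], list(means = 1:3, sds = 1:3,
                                                keep = 1:3, d = 5,
                                                names = c("p", "q", "r"))),
               "retained set")
})

test_that("training maximizes the variational score above linear TICA", {
  tr <- slowDoubleWellRun()
  x <- tr@frames[, 1, 1]
  ## nonlinear feature bank: the basin indicator is not a linear function
  X <- cbind(x, x^2, sin(2 * x), exp(-x))
  colnames(X) <- paste0("f", 1:4)
  nT <- floor(0.8 * nrow(X))
  cfg <- trainConfig(lag = 20, maxEpochs = 150, seed = 13)
  model <- trainDeepTica(X, cfg, zref = x)
  expect_equal(nrow(model@trainLog) >= 1, TRUE)

  ## architecture: parameter count of dense [d,128,64,4] with biases
  d <- ncol(X)
  expect_equal(nParameters(model),
               (d * 128 + 128) + (128 * 64 + 64) + (64 * 4 + 4))

  ## validation-split comparison at the same lag: generalized Rayleigh
  ## quotient of each model's 1D projection
  val <- (nT + 1):nrow(X)
  ray <- function(series) {
    cv <- laggedCovariances(matrix(series, ncol = 1), 20)
    cv@Ct / cv@C0
  }
  lin <- solveTica(laggedCovariances(X[1:nT, ], 20), 1)
  evDeep <- ray(evaluateCv(model, X)[val])
  evLin <- ray(ticaProject(lin, X)[val, 1])
  ## bootstrap SE of the validation eigenvalue difference
  bl <- split(val, cut(seq_along(val), 10))
  evs <- vapply(bl, function(i) ray(evaluateCv(model, X)[i]) -
                  ray(ticaProject(lin, X)[i, 1]), 1)
  se <- sd(evs) / sqrt(length(evs))
  expect_gte(evDeep, evLin - 3 * se)

  ## CV tracks the basin label and is affinely pinned to [-1, 1].
  ## Spearman against a binary label is capped at sqrt(3*p*q)*2 (~0.866
  ## when balanced) even for a perfectly separating CV, so the check is
  ## made relative to that ceiling, alongside the ROC area.
  cv <- evaluateCv(model, X)
  ceiling <- cor(sign(x) + seq_along(x) * 1e-12, sign(x),
                 method = "spearman")
  expect_gt(abs(cor(cv, sign(x), method = "spearman")), 0.95 * ceiling)
  expect_gt(memfes:::rocAuc(cv, x > 0), 0.99)
  expect_equal(range(cv), c(-1, 1), tolerance = 1e-9)
  ## sign convention: the max-zref frame maps to the water (positive) side
  expect_gt(cv[which.max(x)], 0)
  expect_gt(mean(cv[x > 0]), 0)
  expect_lt(mean(cv[x < 0]), 0)

  ## Bhattacharyya overlap of the CV between labeled basins < 0.2
  br <- seq(-1.001, 1.001, length.out = 41)
  p <- hist(cv[x > 0], breaks = br, plot = FALSE)$density
  q <- hist(cv[x < 0], breaks = br, plot = FALSE)$density
  p <- p / sum(p); q <- q / sum(q)
  expect_lt(sum(sqrt(p * q)), 0.2)

  ## deterministic retraining
  model2 <- trainDeepTica(X, cfg, zref = x)
  expect_identical(model@trainLog, model2@trainLog)
  expect_equal(evaluateCv(model2, X), cv, tolerance = 1e-12)
})

test_that("CV gradients match central differences", {
  tr <- slowDoubleWellRun()
  x <- tr@frames[, 1, 1]
  X <- cbind(x, x^2, sin(2 * x), exp(-x))
  model <- trainDeepTica(X, trainConfig(lag = 20, maxEpochs = 30, seed = 1),
                         zref = x)
  set.seed(9)
  for (r in sample(nrow(X), 20)) {
    ev <- evaluateCv(model, X[r, ], gradient = TRUE)
    num <- vapply(seq_len(ncol(X)), function(i) {
      h <- 1e-5
      xp <- X[r, ]; xp[i] <- xp[i] + h
      xm <- X[r, ]; xm[i] <- xm[i] - h
      (evaluateCv(model, xp) - evaluateCv(model, xm)) / (2 * h)
    }, 1)
    expect_lt(max(abs(num - ev$grad)), 1e-4)
  }
})

test_that("model export is bit-faithful, self-describing and tamper-evident", {
  tr <- slowDoubleWellRun()
  x <- tr@frames[, 1, 1]
  X <- cbind(x, x^2, sin(2 * x), exp(-x))
  model <- trainDeepTica(X, trainConfig(lag = 20, maxEpochs = 10, seed = 2),
                         zref = x)
  f <- withr::local_tempfile(fileext = ".json")
  exportModel(model, f)
  m2 <- loadModel(f)
  idx <- seq(1, nrow(X), length.out = 100)
  expect_equal(evaluateCv(m2, X[idx, ]), evaluateCv(model, X[idx, ]),
               tolerance = 1e-12)
  ## the file self-describes the layer widths
  meta <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(as.integer(meta$arch), c(4L, 128L, 64L, 4L))
  ## tampering with a stored weight breaks the checksum
  meta$weights$W1$data[1] <- meta$weights$W1$data[1] + 1e-3
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(meta, f2, digits = NA, auto_unbox = TRUE)
  expect_error(loadModel(f2), "checksum")
  ## wrong version refused
  meta2 <- jsonlite::read_json(f, simplifyVector = TRUE)
  meta2$version <- 99L
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(meta2, f3, digits = NA, auto_unbox = TRUE)
  expect_error(loadModel(f3), "version")
})
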