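#' Build an end-to-end protocol configuration
#'
#' Encodes the two-phase run plan: multithermal exploration with shared
#' bias (phase 1), descriptor featurization after a discard, Deep-TICA
#' training, OPES MetaD along the learned CV with shared-bias walkers
#' (phase 2), reweighted FES / basin analysis along both the z-distance
#' and the learned CV, and an optional binding comparison.
#'
#' Defaults follow the full run plan (8 walkers per phase, 2e5 then 1e5
#' steps); tests and the worked examples pass reduced lengths explicitly.
#'
#' @param spec a [PotentialSpec-class] (mini-bilayer or 2D insertion toy)
#' @param phase1,phase2 lists: `steps`, `walkers`, `dt`, `temperature`,
#'   `friction`, `stride` (recording), `depStride` (deposition)
#' @param discardFrac initial fraction of phase-1 frames discarded before
#'   CV training
#' @param train a [trainConfig()]
#' @param fes list: `zGrid`, `cvGrid`, `zRanges`, `cvRanges` (basin
#'   definitions, `A` = water, `B` = membrane)
#' @param binding `NULL`, a CSV path, or a list of synthetic-titration
#'   parameters (`A`, `KD`, `noiseSd`, `nReplicates`, `temperature`)
#' @param seed global seed; fanned out per stage by a counter-based
#'   splitter
#' @return a [ProtocolConfig-class]
#' @export
protocolConfig <- function(spec = miniBilayerSpec(),
                           phase1 = list(), phase2 = list(),
                           discardFrac = 0.1,
                           train = trainConfig(),
                           fes = list(), binding = NULL, seed = 1L) {
  p1 <- utils::modifyList(list(steps = 2e5, walkers = 8L, dt = 0.02,
                               temperature = 310, friction = 1,
                               stride = 50L, depStride = 500L,
                               tempRange = c(270, 500), nGrid = 64L), phase1)
  p2 <- utils::modifyList(list(steps = 1e5, walkers = 8L, dt = 0.02,
                               temperature = 310, friction = 1,
                               stride = 50L, depStride = 500L,
                               barrier = 60, sigmaMin = 0.028,
                               softminBeta = 50), phase2)
  w <- if (spec@kind == "mini_bilayer") spec@params$slabHalfWidth else NA
  fdef <- if (spec@kind == "mini_bilayer") {
    list(zGrid = seq(-5, 5, length.out = 101),
         cvGrid = seq(-1.3, 1.3, length.out = 101),
         zRanges = list(A = c(w + 0.4, 5), B = c(-w, w)),
         cvRanges = NULL)
  } else {
    a <- spec@params$a
    list(zGrid = seq(-2.5 * a, 2.5 * a, length.out = 101),
         cvGrid = seq(-1.3, 1.3, length.out = 101),
         zRanges = list(A = c(0.25 * a, 2.5 * a), B = c(-2.5 * a, -0.25 * a)),
         cvRanges = NULL)
  }
  fes <- utils::modifyList(fdef, fes)
  if (is.list(binding))
    binding <- utils::modifyList(list(A = 120, KD = 0.013, noiseSd = 2,
                                      nReplicates = 5, temperature = 298.15),
                                 binding)
  new("ProtocolConfig", spec = spec, phase1 = p1, phase2 = p2,
      discardFrac = discardFrac, train = unclass(train), fes = fes,
      binding = if (is.null(binding)) list() else
        if (is.character(binding)) list(csv = binding) else binding,
      seed = as.integer(seed))
}

#' Read a protocol configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the [protocolConfig()]
#'   arguments, with `spec: {kind: ..., ...}` dispatched to the matching
#'   spec constructor
#' @return a [ProtocolConfig-class]
#' @export
readProtocolConfig <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(switch(y$spec$kind,
                         double_well_1d = doubleWellSpec,
                         insertion_2d = insertionSpec,
                         mini_bilayer = miniBilayerSpec),
                  y$spec[setdiff(names(y$spec), "kind")])
  protocolConfig(spec = spec, phase1 = y$phase1 %||% list(),
                 phase2 = y$phase2 %||% list(),
                 discardFrac = y$discardFrac %||% 0.1,
                 train = do.call(trainConfig, y$train %||% list()),
                 fes = y$fes %||% list(), binding = y$binding,
                 seed = y$seed %||% 1L)
}

## Analytic toys use the bare coordinates as "descriptors": x doubles as
## the z-distance analogue and y as the orientation-like coordinate.
#' @noRd
.coordDescriptors <- function(traj, discard = 0) {
  keep <- which(traj@times > discard)
  if (!length(keep)) stop("no frames remain after discard")
  X <- traj@frames[keep, 1, , drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  colnames(X) <- c("x", "y", "z")[seq_len(ncol(X))]
  aux <- data.frame(
    time = traj@times[keep],
    z_dist = X[, 1],
    z_dipole = if (ncol(X) >= 2) X[, 2] else 0,
    logweight = traj@bias[keep] / .kBT(traj@temperature),
    label = as.character(basinLabels(traj))[keep],
    walker = traj@walker)
  new("DescriptorSet", values = X, aux = aux,
      nBeads = ncol(X), nGroups = 1L)
}

## CV-as-a-function-of-coordinates closure: featurize one frame (softmin
## for differentiability), evaluate the model, chain the gradients back to
## the coordinates.
#' @noRd
.cvCallable <- function(model, system, groups = NULL, beta = 50) {
  if (system@spec@kind == "mini_bilayer") {
    if (is.null(groups)) groups <- defaultGroupSpec(system)
    validObject(groups)
    function(x) {
      f <- minDistanceFeatures(x, groups, system@box, system@periodic,
                               beta = beta)
      ev <- evaluateCv(model, f, gradient = TRUE)
      grad <- .minDistanceChainGrad(x, groups, system@box, system@periodic,
                                    beta, ev$grad)
      list(value = ev$value, grad = grad)
    }
  } else {
    function(x) {
      ev <- evaluateCv(model, as.numeric(x), gradient = TRUE)
      list(value = ev$value, grad = matrix(ev$grad, nrow(x), ncol(x)))
    }
  }
}

## trajectory -> per-frame (z, cv) series for the FES stage
#' @noRd
.frameSeries <- function(traj, model, groups = NULL) {
  sys <- traj@system
  T <- dim(traj@frames)[1]
  z <- numeric(T)
  if (sys@spec@kind == "mini_bilayer") {
    for (t in seq_len(T))
      z[t] <- zDistance(traj@frames[t, , ], sys@soluteIdx, sys@membraneIdx,
                        sys@masses)
  } else {
    z <- traj@frames[, 1, 1]
  }
  cv <- traj@cv
  if (all(is.na(cv))) {
    if (sys@spec@kind == "mini_bilayer") {
      if (is.null(groups)) groups <- defaultGroupSpec(sys)
      cv <- vapply(seq_len(T), function(t)
        evaluateCv(model, minDistanceFeatures(traj@frames[t, , ], groups,
                                              sys@box, sys@periodic,
                                              beta = 50)), numeric(1))
    } else {
      cv <- vapply(seq_len(T), function(t)
        evaluateCv(model, as.numeric(traj@frames[t, , ])), numeric(1))
    }
  }
  list(z = z, cv = cv)
}

#' Run the full exploration-to-comparison protocol
#'
#' Executes: (1) OPES expanded multithermal exploration with shared-bias
#' walkers; (2) descriptor featurization with discard; (3) Deep-TICA
#' training; (4) OPES MetaD along the learned CV with shared-bias walkers;
#' (5) reweighted FES along the z-distance and along the CV, with basin
#' dG, barriers and path-independence report; (6) optional binding-fit
#' comparison. Per-stage checkpoints are written under `outDir` (when
#' given) and reused on resume, so an interrupted run reproduces the
#' uninterrupted report.
#'
#' @param config a [ProtocolConfig-class]
#' @param outDir optional checkpoint/output directory
#' @param resume reuse existing checkpoints in `outDir`
#' @param verbose print stage progress
#' @return a report list (also serialized to `outDir/report.json` when
#'   `outDir` is given)
#' @export
runProtocol <- function(config, outDir = NULL, resume = TRUE,
                        verbose = FALSE) {
  validObject(config)
  cfgHash <- textChecksum(paste(deparse(list(
    config@spec@kind, config@spec@params, config@phase1, config@phase2,
    config@discardFrac, config@train, config@fes, config@binding,
    config@seed)), collapse = ""))
  ck <- function(name) if (is.null(outDir)) NULL else
    file.path(outDir, paste0(name, "-", cfgHash, ".rds"))
  stage <- function(name, fun) {
    f <- ck(name)
    if (!is.null(f) && resume && file.exists(f)) {
      if (verbose) message("[", name, "] resumed from checkpoint")
      return(readRDS(f))
    }
    if (verbose) message("[", name, "] running")
    val <- fun()
    if (!is.null(f)) {
      dir.create(dirname(f), showWarnings = FALSE, recursive = TRUE)
      saveRDS(val, f)
    }
    val
  }
  sys <- buildSystem(config@spec, seed = splitSeed(config@seed, 1L))
  p1 <- config@phase1; p2 <- config@phase2

  explore <- stage("explore", function() {
    st <- newExpandedState(tempRange = p1$tempRange, nGrid = p1$nGrid,
                           temperature = p1$temperature,
                           stride = p1$depStride)
    eng <- expandedEngine(st, sys, temperature = p1$temperature)
    runSharedBias(sys, eng, nWalkers = p1$walkers, steps = p1$steps,
                  seeds = vapply(seq_len(p1$walkers),
                                 function(w) splitSeed(config@seed, 10L + w),
                                 1L),
                  dt = p1$dt, temperature = p1$temperature,
                  friction = p1$friction, stride = p1$stride)
  })

  feat <- stage("featurize", function() {
    discard <- config@discardFrac * p1$steps * p1$dt
    builder <- if (config@spec@kind == "mini_bilayer")
      function(tr) buildDescriptorMatrix(tr, groups = NULL,
                                         discard = discard)
    else function(tr) .coordDescriptors(tr, discard = discard)
    bindDescriptors(lapply(explore$trajectories, builder))
  })

  model <- stage("traincv", function() {
    cfg <- do.call(trainConfig, utils::modifyList(
      config@train, list(seed = splitSeed(config@seed, 2L))))
    trainDeepTica(feat, cfg)
  })

  sampled <- stage("sample", function() {
    cv <- .cvCallable(model, sys, beta = p2$softminBeta)
    sigma0 <- estimateSigma0(sys, cv, nSteps = 2000, dt = p2$dt,
                             temperature = p2$temperature,
                             friction = p2$friction,
                             seed = splitSeed(config@seed, 3L))
    st <- newOpesState(barrier = p2$barrier, temperature = p2$temperature,
                       sigma0 = max(sigma0, p2$sigmaMin),
                       sigmaMin = p2$sigmaMin, stride = p2$depStride)
    eng <- opesEngine(st, cv, temperature = p2$temperature)
    runSharedBias(sys, eng, nWalkers = p2$walkers, steps = p2$steps,
                  seeds = vapply(seq_len(p2$walkers),
                                 function(w) splitSeed(config@seed, 20L + w),
                                 1L),
                  dt = p2$dt, temperature = p2$temperature,
                  friction = p2$friction, stride = p2$stride)
  })

  analysis <- stage("fes", function() {
    series <- lapply(sampled$trajectories, .frameSeries, model = model)
    z <- unlist(lapply(series, `[[`, "z"))
    cv <- unlist(lapply(series, `[[`, "cv"))
    w <- unlist(lapply(sampled$trajectories, frameWeights))
    blocks <- unlist(mapply(function(tr, k) rep(k, length(tr@times)),
                            sampled$trajectories,
                            seq_along(sampled$trajectories),
                            SIMPLIFY = FALSE))
    fz <- fesNd(z, w, grid = config@fes$zGrid,
                temperature = p2$temperature, blocks = blocks,
                cvNames = "z_dist")
    fc <- fesNd(cv, w, grid = config@fes$cvGrid,
                temperature = p2$temperature, blocks = blocks,
                cvNames = "deep_tica_1")
    cvRanges <- config@fes$cvRanges
    if (is.null(cvRanges)) {
      gcv <- config@fes$cvGrid
      h <- diff(gcv[1:2])
      cvRanges <- tryCatch(
        cvBasinRanges(evaluateCv(model, feat@values), feat@aux$label, gcv),
        error = function(e) {
          ## exploration saw a single basin: fall back to the sign
          ## convention's natural split at CV = 0
          warning("single-basin exploration; CV basins split at 0")
          list(A = c(h, max(gcv) + h), B = c(min(gcv) - h, -h))
        })
    }
    cmp <- compareCvFes(fz, fc, config@fes$zRanges, cvRanges)
    list(fesZ = fz, fesCv = fc, compare = cmp, cvRanges = cvRanges)
  })

  cvPlane <- validateCvPlane(feat, model)

  bindingReport <- NULL
  if (length(config@binding)) {
    b <- config@binding
    dat <- if (!is.null(b$csv)) readBindingCsv(b$csv) else
      generateBindingData(A = b$A, KD = b$KD, noiseSd = b$noiseSd,
                          nReplicates = b$nReplicates,
                          seed = splitSeed(config@seed, 4L))
    fit <- bindingFreeEnergy(fitBinding(dat),
                             temperature = b$temperature %||% 298.15)
    bindingReport <- list(
      fit = list(F0 = fit@F0, A = fit@A, kd = fit@kd, kdSe = fit@kdSe,
                 dG = fit@dG, dGse = fit@dGse),
      comparison = compareAffinities(
        c(toy = analysis$compare$dG_cv),
        c(toy = fit@dG)))
  }

  report <- list(
    configHash = cfgHash, seed = config@seed,
    system = list(kind = config@spec@kind, nDof = nDof(sys)),
    exploration = list(walkers = length(explore$trajectories),
                       events = explore$events),
    deepTica = list(eigenvalues = model@evals,
                    leadingLinearTica = attr(cvPlane, "linearEval"),
                    epochs = nrow(model@trainLog),
                    bestValidLoss = min(model@trainLog$valid)),
    cvDiagnostics = list(rocAuc = attr(cvPlane, "auc"),
                         signConvention = attr(cvPlane, "signOk")),
    sampling = list(walkers = length(sampled$trajectories),
                    kernels = nrow(sampled$state@kernels),
                    events = sampled$events),
    fes = list(
      dG_z = analysis$compare$dG_z, se_z = analysis$compare$se_z,
      dG_cv = analysis$compare$dG_cv, se_cv = analysis$compare$se_cv,
      dG_agree = analysis$compare$dG_agree,
      barrier_z = analysis$compare$barrier_z,
      barrier_cv = analysis$compare$barrier_cv,
      minima_z = analysis$compare$basins$z@minima),
    binding = bindingReport)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeFes(analysis$fesZ, file.path(outDir, "fes_z.dat"))
    writeFes(analysis$fesCv, file.path(outDir, "fes_cv.dat"))
    utils::write.csv(cvPlane, file.path(outDir, "cv_plane.csv"),
                     row.names = FALSE)
  }
  attr(report, "objects") <- list(model = model, analysis = analysis,
                                  descriptors = feat, sampled = sampled)
  report
}

#' Data-driven basin ranges on a learned-CV axis
#'
#' The affine [-1, 1] scaling of a learned CV is set by the extreme
#' training frames, so the bulk of each basin need not sit near the
#' endpoints. Basin ranges for free-energy integrals are therefore placed
#' around the CV value that separates the labeled basins: the midpoint of
#' the label-conditional medians.
#'
#' @param cv CV values of labeled reference frames
#' @param labels "water"/"membrane" labels for those frames
#' @param grid CV grid the FES will use
#' @return list with basin ranges `A` (water side) and `B` (membrane side)
#' @export
cvBasinRanges <- function(cv, labels, grid) {
  mw <- stats::median(cv[labels == "water"])
  mm <- stats::median(cv[labels == "membrane"])
  if (!is.finite(mw) || !is.finite(mm))
    stop("both basin labels required to place CV basin ranges")
  cstar <- (mw + mm) / 2
  h <- diff(grid[1:2])
  list(A = sort(c(cstar + h, max(grid) + h)),
       B = sort(c(min(grid) - h, cstar - h)))
}

#' CV validation plane (z-distance, z-dipole, Deep-TICA 1)
#'
#' Emits the three-column scatter table used to judge whether the learned
#' CV separates the metastable states in the physically interpretable
#' plane, plus a basin-separation score: the area under the ROC curve of
#' the CV against the ground-truth basin labels and whether the sign
#' convention (+1 = water) holds.
#'
#' @param desc a [DescriptorSet-class] with labeled aux columns
#' @param model a [DeepTicaModel-class] trained on compatible descriptors
#' @return data.frame `(z_dist, z_dipole, deep_tica_1)` with attributes
#'   `auc`, `signOk`, and `linearEval` (leading linear-TICA eigenvalue on
#'   the same data and lag, for the variational comparison)
#' @export
validateCvPlane <- function(desc, model) {
  cv <- evaluateCv(model, desc@values)
  out <- data.frame(z_dist = desc@aux$z_dist, z_dipole = desc@aux$z_dipole,
                    deep_tica_1 = cv)
  lab <- desc@aux$label
  auc <- NA_real_
  signOk <- NA
  if (!all(is.na(lab)) && length(unique(stats::na.omit(lab))) == 2) {
    water <- lab == "water"
    auc <- rocAuc(cv, water)
    signOk <- mean(cv[water]) > 0 && mean(cv[!water]) < 0
  }
  lin <- tryCatch({
    lw <- desc@aux$logweight
    wts <- if (all(lw == 0)) NULL else exp(lw - max(lw))
    cov <- suppressWarnings(laggedCovariances(desc@values, model@lag,
                                              weights = wts))
    solveTica(cov, nModes = 1L)@evals[1]
  }, error = function(e) NA_real_)
  attr(out, "auc") <- auc
  attr(out, "signOk") <- signOk
  attr(out, "linearEval") <- lin
  out
}
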