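## small hand-built frame: 2 "solute" beads + 4 sites in two groups,
## periodic x,y box 5 x 5, aperiodic z
frameFixture <- function() {
  frame <- rbind(c(1.0, 1.0, 2.0),    # site g1
                 c(1.8, 1.0, 2.0),    # site g1
                 c(4.9, 1.0, 2.0),    # site g2 (wraps to bead 1)
                 c(2.5, 2.5, 0.0),    # site g2
                 c(1.0, 1.0, 2.0),    # bead 1: coincident with site 1
                 c(1.0, 1.0, 3.3))    # bead 2
  list(frame = frame, box = c(5, 5, Inf), periodic = c(TRUE, TRUE, FALSE),
       groups = groupSpec(5:6, list(g1 = 1:2, g2 = 3:4)))
}

test_that("minimum-distance features match their definition and the all-pairs oracle", {
  fx <- frameFixture()
  f <- minDistanceFeatures(fx$frame, fx$groups, fx$box, fx$periodic)
  expect_equal(unname(f["min_d.b1.g1"]), 0)                    # coincident
  expect_equal(unname(f["min_d.b2.g1"]), 1.3)                  # min(1.3, sqrt(0.64+1.69))
  expect_equal(unname(f["min_d.b1.g2"]), 1.1)                  # minimum image in x
  expect_error(minDistanceFeatures(fx$frame,
                                   groupSpec(5:6, list(g1 = 1:2, g2 = integer())),
                                   fx$box, fx$periodic), "empty")

  ## brute-force all-pairs oracle on random frames
  sys <- buildSystem(miniBilayerSpec(), 1)
  gs <- defaultGroupSpec(sys)
  set.seed(77)
  for (r in 1:10) {
    fr <- coordinates(sys) + matrix(rnorm(nDof(sys), sd = 0.3),
                                    nrow(coordinates(sys)), 3)
    fr[, 1] <- fr[, 1] %% sys@box[1]; fr[, 2] <- fr[, 2] %% sys@box[2]
    f1 <- minDistanceFeatures(fr, gs, sys@box, sys@periodic)
    brute <- unlist(lapply(seq_along(gs@soluteIdx), function(b) {
      vapply(gs@groups, function(idx) {
        min(vapply(idx, function(j) {
          dd <- fr[gs@soluteIdx[b], ] - fr[j, ]
          dd[1] <- minImage(dd[1], sys@box[1]); dd[2] <- minImage(dd[2], sys@box[2])
          sqrt(sum(dd^2))
        }, 1))
      }, 1)
    }))
    expect_equal(unname(f1), unname(brute), tolerance = 1e-12)
  }
})

test_that("feature invariances: group permutation, PBC displacement, softmin bound", {
  sys <- buildSystem(miniBilayerSpec(), 2)
  gs <- defaultGroupSpec(sys)
  fr <- coordinates(sys)
  f0 <- minDistanceFeatures(fr, gs, sys@box, sys@periodic)
  ## shuffle site order within groups
  gs2 <- groupSpec(gs@soluteIdx, lapply(gs@groups, rev))
  expect_equal(unname(minDistanceFeatures(fr, gs2, sys@box, sys@periodic)),
               unname(f0))
  ## displace one lipid site by a lattice vector
  fr2 <- fr
  fr2[3, 1] <- fr2[3, 1] + sys@box[1]
  fr2[, 1] <- fr2[, 1] %% sys@box[1]
  expect_equal(minDistanceFeatures(fr2, gs, sys@box, sys@periodic), f0,
               tolerance = 1e-12)
  ## softmin >= hard min, monotone convergence from above
  prev <- Inf
  for (beta in c(5, 20, 80, 320, 1280)) {
    fs <- minDistanceFeatures(fr, gs, sys@box, sys@periodic, beta = beta)
    expect_true(all(fs >= f0 - 1e-9))
    expect_true(all(fs <= prev + 1e-9))
    prev <- fs
  }
  expect_lt(max(abs(prev - f0)), 0.01)
})

test_that("z-distance and z-dipole match direct center-of-mass arithmetic", {
  set.seed(5)
  for (r in 1:20) {
    fr <- matrix(rnorm(30), 10, 3)
    zd <- zDistance(fr, 1:4, 5:10)
    expect_equal(zd, mean(fr[1:4, 3]) - mean(fr[5:10, 3]), tolerance = 1e-12)
    ## rigid z-translation leaves the relative coordinate unchanged
    fr2 <- fr; fr2[, 3] <- fr2[, 3] + 3.7
    expect_equal(zDistance(fr2, 1:4, 5:10), zd, tolerance = 1e-12)
  }
  fr <- matrix(0, 4, 3)
  expect_equal(zDipole(fr, 1:4, rep(0, 4)), 0)
  ## point dipole: +/-1e separated by 1 nm along z
  fr2 <- rbind(c(0, 0, 0.5), c(0, 0, -0.5))
  expect_equal(zDipole(fr2, 1:2, c(1, -1)), 1)
  expect_equal(zDipole(fr2, 1:2, c(-1, 1)), -1)
  ## mirror through the COM plane flips the sign, preserves magnitude
  set.seed(6)
  fr3 <- matrix(rnorm(15), 5, 3)
  q <- c(-1, 0, 0, 1, 1)
  zc <- mean(fr3[, 3])
  fr3m <- fr3; fr3m[, 3] <- 2 * zc - fr3m[, 3]
  expect_equal(zDipole(fr3m, 1:5, q), -zDipole(fr3, 1:5, q), tolerance = 1e-12)
  expect_error(zDipole(fr3, 1:5, c(1, -1)), "charge")
})

test_that("descriptor matrices have the aminosterol-system dimensions and round-trip COLVAR", {
  mb <- miniBilayerTrained()
  tr <- mb$run$trajectories[[1]]
  d <- buildDescriptorMatrix(tr, discard = 0)
  expect_equal(ncol(descriptorValues(d)), 15 * 12)   # 180-descriptor system
  expect_equal(nrow(descriptorValues(d)), dim(tr@frames)[1])
  ## B = 14 analogue gives the 168-descriptor set
  sys14 <- buildSystem(miniBilayerSpec(soluteBeads = 14L), 1)
  tr14 <- runLangevin(sys14, nSteps = 200, dt = 0.02, temperature = 310,
                      seed = 2, stride = 50L)
  expect_equal(ncol(descriptorValues(buildDescriptorMatrix(tr14))), 14 * 12)
  expect_error(buildDescriptorMatrix(tr, discard = 1e9), "discard")
  ## CHOL/GM1 analogues excluded from groups but present in the system
  gs <- defaultGroupSpec(mb$sys)
  expect_false(any(grepl("CHOL|GM1", names(gs@groups))))
  expect_true(any(grepl("CHOL", mb$sys@siteTypes)))

  f <- withr::local_tempfile(fileext = ".dat")
  writeDescriptors(d, f)
  d2 <- readDescriptors(f)
  expect_equal(descriptorValues(d2), descriptorValues(d), tolerance = 1e-9)
  expect_equal(d2@aux$z_dist, d@aux$z_dist, tolerance = 1e-9)
})

test_that("XYZ trajectories round-trip", {
  sys <- buildSystem(miniBilayerSpec(), 1)
  tr <- runLangevin(sys, nSteps = 100, dt = 0.02, temperature = 310,
                    seed = 1, stride = 25L)
  f <- withr::local_tempfile(fileext = ".xyz")
  writeXyz(tr, f)
  back <- readXyz(f)
  expect_equal(dim(back$frames), dim(tr@frames))
  expect_equal(back$frames, tr@frames, tolerance = 1e-7)
  expect_equal(back$times, tr@times, tolerance = 1e-6)
})
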