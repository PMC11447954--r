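## Interface/slab shape parameters shared by energy and force evaluation.
.SLAB_SOFT <- 0.25   # slab indicator softness (nm)
.IFACE_SD <- 0.25    # interfacial barrier width (nm)
.WALL_K <- 50        # confining wall stiffness (kJ/mol/nm^2)
.WALL_PAD <- 0.5     # wall offset from the box edge (nm)

#' Build a toy system from a potential specification
#'
#' Deterministic given `(spec, seed)`. For the mini-bilayer, typed lipid
#' sites are placed on a jittered symmetric slab lattice about z = 0 and the
#' solute chain in the water region; overlapping lattice draws are
#' rejection-resampled a bounded number of times before failing.
#'
#' @param spec a [PotentialSpec-class]
#' @param seed integer build seed
#' @return a [ToySystem-class] with analytic energy/force via [energyForce()]
#' @examples
#' sys <- buildSystem(doubleWellSpec(), seed = 1)
#' energyForce(sys, coordinates(sys))
#' @export
buildSystem <- function(spec, seed = 1L) {
  validObject(spec)
  p <- spec@params
  if (spec@kind == "harmonic_1d") {
    return(new("ToySystem", spec = spec,
               coords0 = matrix(0, 1, 1), box = Inf, periodic = FALSE,
               masses = 1, soluteIdx = 1L, membraneIdx = integer(),
               charges = 0, siteTypes = character(),
               tether = matrix(0, 0, 0), seed = as.integer(seed)))
  }
  if (spec@kind == "double_well_1d") {
    return(new("ToySystem", spec = spec,
               coords0 = matrix(p$a, 1, 1), box = Inf, periodic = FALSE,
               masses = 1, soluteIdx = 1L, membraneIdx = integer(),
               charges = 0, siteTypes = character(),
               tether = matrix(0, 0, 0), seed = as.integer(seed)))
  }
  if (spec@kind == "insertion_2d") {
    return(new("ToySystem", spec = spec,
               coords0 = matrix(c(p$a, 0), 1, 2), box = c(Inf, Inf),
               periodic = c(FALSE, FALSE), masses = 1, soluteIdx = 1L,
               membraneIdx = integer(), charges = 0,
               siteTypes = character(), tether = matrix(0, 0, 0),
               seed = as.integer(seed)))
  }
  ## mini_bilayer
  G <- p$nLipidTypes; E <- p$nExcludedTypes; S <- p$sitesPerType
  B <- p$soluteBeads; w <- p$slabHalfWidth; box <- p$box
  nDOPC <- ceiling(0.6 * G)
  typeNames <- c(paste0("DOPC_", seq_len(nDOPC)),
                 paste0("SM_", seq_len(G - nDOPC)),
                 if (E > 0) paste0(rep(c("CHOL", "GM1"), length.out = E),
                                   "_", seq_len(E)))
  nTypes <- G + E
  M <- nTypes * S
  siteTypes <- rep(typeNames, each = S)
  ## z-plane per type: spread tether planes through the slab, mirrored per
  ## leaflet; site j of a type alternates leaflets -> symmetric slab.
  zlev <- seq(0.9, 0.15, length.out = nTypes) * w
  leaflet <- rep(c(1, -1), length.out = S)
  tz <- as.vector(vapply(seq_len(nTypes),
                         function(g) leaflet * zlev[g], numeric(S)))
  ## lay the sites per leaflet on a square x,y grid
  tether <- matrix(0, M, 3)
  tether[, 3] <- tz
  for (lf in c(1, -1)) {
    idx <- which(rep(leaflet, nTypes) == lf)
    n <- length(idx)
    side <- ceiling(sqrt(n))
    gx <- ((seq_len(n) - 1) %% side + 0.5) / side * box[1]
    gy <- ((seq_len(n) - 1) %/% side + 0.5) / side * box[2]
    tether[idx, 1] <- gx
    tether[idx, 2] <- gy
  }
  withSeed(seed, {
    placed <- FALSE
    for (try in seq_len(25)) {
      jit <- tether
      jit[, 1:2] <- jit[, 1:2] + matrix(stats::runif(2 * M, -0.1, 0.1), M, 2)
      jit[, 1] <- jit[, 1] %% box[1]
      jit[, 2] <- jit[, 2] %% box[2]
      dmin <- Inf
      for (i in seq_len(M - 1)) {
        dx <- minImage(jit[(i + 1):M, 1] - jit[i, 1], box[1])
        dy <- minImage(jit[(i + 1):M, 2] - jit[i, 2], box[2])
        dz <- jit[(i + 1):M, 3] - jit[i, 3]
        dmin <- min(dmin, sqrt(dx^2 + dy^2 + dz^2))
      }
      if (dmin > 0.05) { placed <- TRUE; break }
    }
    if (!placed)
      stop("mini_bilayer lattice: overlapping sites persist after 25 ",
           "rejection resamples (", M, " sites in ",
           box[1], " x ", box[2], " nm box)")
    solute <- matrix(0, B, 3)
    solute[, 1] <- (0.2 + (seq_len(B) - 1) * p$r0Bond) %% box[1]
    solute[, 2] <- box[2] / 2
    solute[, 3] <- w + 1.7
    coords0 <- rbind(jit, solute)
  })
  new("ToySystem", spec = spec, coords0 = coords0,
      box = c(box[1], box[2], Inf), periodic = c(TRUE, TRUE, FALSE),
      masses = rep(1, M + B), soluteIdx = M + seq_len(B),
      membraneIdx = seq_len(M), charges = p$charges,
      siteTypes = siteTypes, tether = tether, seed = as.integer(seed))
}

#' @describeIn buildSystem initial coordinates of a system
#' @param system a [ToySystem-class]
#' @export
coordinates <- function(system) system@coords0

#' @describeIn buildSystem number of configurational degrees of freedom
#' @export
nDof <- function(system) length(system@coords0)

#' Potential energy and analytic forces of a toy system
#'
#' Forces are the exact negative gradient of the analytic potential;
#' periodic axes use the minimum-image convention.
#'
#' @param system a [ToySystem-class]
#' @param coords N x nDim coordinate matrix (nm)
#' @return list with `energy` (kJ/mol) and `forces` (kJ/mol/nm, same shape
#'   as `coords`)
#' @export
energyForce <- function(system, coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates passed to energyForce")
  if (!identical(dim(coords), dim(system@coords0)))
    stop("coordinate shape mismatch: expected ",
         paste(dim(system@coords0), collapse = "x"))
  p <- system@spec@params
  switch(system@spec@kind,
    harmonic_1d = list(energy = 0.5 * p$k * coords[1, 1]^2,
                       forces = matrix(-p$k * coords[1, 1], 1, 1)),
    double_well_1d = .efDoubleWell(coords, p),
    insertion_2d = .efInsertion(coords, p),
    mini_bilayer = .efMiniBilayer(system, coords, p))
}

## 1D tilted quartic: U = h((x/a)^2-1)^2 - (dG/2) tanh(x/(0.25 a))
#' @noRd
.dwU <- function(x, h, a, dG) {
  h * ((x / a)^2 - 1)^2 - (dG / 2) * tanh(x / (0.25 * a))
}
#' @noRd
.dwDU <- function(x, h, a, dG) {
  4 * h * x * ((x / a)^2 - 1) / a^2 -
    (dG / 2) / (0.25 * a) / cosh(x / (0.25 * a))^2
}

#' @noRd
.efDoubleWell <- function(coords, p) {
  x <- coords[1, 1]
  list(energy = .dwU(x, p$barrier, p$a, p$deltaG),
       forces = matrix(-.dwDU(x, p$barrier, p$a, p$deltaG), 1, 1))
}

#' @noRd
.efInsertion <- function(coords, p) {
  x <- coords[1, 1]; y <- coords[1, 2]
  s <- x + p$coupling * y
  dUds <- .dwDU(s, p$barrier, p$a, p$deltaG)
  e <- .dwU(s, p$barrier, p$a, p$deltaG) + 0.5 * p$kOrth * y^2
  list(energy = e,
       forces = matrix(c(-dUds, -(dUds * p$coupling + p$kOrth * y)), 1, 2))
}

## Smooth slab indicator and its derivative.
#' @noRd
.slabS <- function(z, w) {
  0.5 * (tanh((w - z) / .SLAB_SOFT) + tanh((w + z) / .SLAB_SOFT))
}
#' @noRd
.slabDS <- function(z, w) {
  0.5 * (-1 / cosh((w - z) / .SLAB_SOFT)^2 +
           1 / cosh((w + z) / .SLAB_SOFT)^2) / .SLAB_SOFT
}

#' @noRd
.efMiniBilayer <- function(system, coords, p) {
  box <- system@box
  M <- length(system@membraneIdx); B <- length(system@soluteIdx)
  mem <- coords[system@membraneIdx, , drop = FALSE]
  sol <- coords[system@soluteIdx, , drop = FALSE]
  F <- matrix(0, nrow(coords), 3)
  U <- 0

  ## lipid tethers (min image in x,y)
  d <- mem - system@tether
  d[, 1] <- minImage(d[, 1], box[1])
  d[, 2] <- minImage(d[, 2], box[2])
  U <- U + 0.5 * p$kTether * sum(d^2)
  F[system@membraneIdx, ] <- F[system@membraneIdx, ] - p$kTether * d

  ## solute bonds
  db <- sol[-1, , drop = FALSE] - sol[-B, , drop = FALSE]
  db[, 1] <- minImage(db[, 1], box[1])
  db[, 2] <- minImage(db[, 2], box[2])
  r <- sqrt(rowSums(db^2))
  U <- U + 0.5 * p$kBond * sum((r - p$r0Bond)^2)
  fb <- -p$kBond * (r - p$r0Bond) / pmax(r, 1e-12) * db
  iS <- system@soluteIdx
  F[iS[-1], ] <- F[iS[-1], ] + fb
  F[iS[-B], ] <- F[iS[-B], ] - fb

  ## per-bead slab background + interfacial barrier + wall
  z <- sol[, 3]; w <- p$slabHalfWidth
  U <- U - p$epsMembrane * sum(.slabS(z, w))
  dUdz <- -p$epsMembrane * .slabDS(z, w)
  gP <- exp(-(z - w)^2 / (2 * .IFACE_SD^2))
  gM <- exp(-(z + w)^2 / (2 * .IFACE_SD^2))
  U <- U + p$interfaceBarrier * sum(gP + gM)
  dUdz <- dUdz + p$interfaceBarrier *
    (-(z - w) / .IFACE_SD^2 * gP - (z + w) / .IFACE_SD^2 * gM)
  zw <- p$box[3] / 2 - .WALL_PAD
  out <- abs(z) > zw
  if (any(out)) {
    U <- U + .WALL_K * sum((abs(z[out]) - zw)^2)
    dUdz[out] <- dUdz[out] + 2 * .WALL_K * (abs(z[out]) - zw) * sign(z[out])
  }
  F[iS, 3] <- F[iS, 3] - dUdz

  ## solute-lipid Gaussian pair wells
  eps <- p$epsPair[match(system@siteTypes, unique(system@siteTypes))]
  dx <- outer(sol[, 1], mem[, 1], "-"); dx <- minImage(dx, box[1])
  dy <- outer(sol[, 2], mem[, 2], "-"); dy <- minImage(dy, box[2])
  dz <- outer(sol[, 3], mem[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  gw <- exp(-r2 / (2 * p$pairRange^2))
  ew <- sweep(gw, 2, eps, "*")               # B x M well depths
  U <- U - sum(ew)
  cf <- ew / p$pairRange^2                    # -dU/dr * (1/r) factor
  F[iS, 1] <- F[iS, 1] - rowSums(cf * dx)
  F[iS, 2] <- F[iS, 2] - rowSums(cf * dy)
  F[iS, 3] <- F[iS, 3] - rowSums(cf * dz)
  F[system@membraneIdx, 1] <- F[system@membraneIdx, 1] + colSums(cf * dx)
  F[system@membraneIdx, 2] <- F[system@membraneIdx, 2] + colSums(cf * dy)
  F[system@membraneIdx, 3] <- F[system@membraneIdx, 3] + colSums(cf * dz)

  list(energy = U, forces = F)
}

#' Ground-truth basin labels for a trajectory
#'
#' For the mini-bilayer the solute is labeled `"membrane"` when the absolute
#' z of its center of mass is below the slab half-width, `"water"`
#' otherwise. For the analytic toys the label is the sign of the slow
#' coordinate (s = x + coupling*y for the 2D insertion model): positive =
#' water.
#'
#' @param traj a [Trajectory-class]
#' @return factor with levels `c("water", "membrane")`
#' @export
basinLabels <- function(traj) {
  sys <- traj@system
  p <- sys@spec@params
  if (sys@spec@kind == "mini_bilayer") {
    z <- apply(traj@frames[, sys@soluteIdx, 3, drop = FALSE], 1, mean)
    lab <- ifelse(abs(z) < p$slabHalfWidth, "membrane", "water")
  } else {
    s <- traj@frames[, 1, 1]
    if (sys@spec@kind == "insertion_2d")
      s <- s + p$coupling * traj@frames[, 1, 2]
    lab <- ifelse(s < 0, "membrane", "water")
  }
  factor(lab, levels = c("water", "membrane"))
}
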