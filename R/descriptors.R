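#' Descriptor group specification for a mini-bilayer system
#'
#' One group per lipid site type, with CHOL/GM1 analogue sites excluded by
#' default (descriptors consider the DOPC and SM analogues only).
#'
#' @param system a mini-bilayer [ToySystem-class]
#' @param exclude regular expression of site-type names to exclude
#' @param cap optional saturation distance (nm); `Inf` disables
#' @return a [GroupSpec-class]
#' @export
defaultGroupSpec <- function(system, exclude = "^(CHOL|GM1)", cap = Inf) {
  types <- unique(system@siteTypes)
  keep <- types[!grepl(exclude, types)]
  groups <- lapply(keep, function(tp) system@membraneIdx[system@siteTypes == tp])
  names(groups) <- keep
  new("GroupSpec", soluteIdx = system@soluteIdx, groups = groups, cap = cap)
}

#' @rdname defaultGroupSpec
#' @param soluteIdx solute bead indices
#' @param groups named list of membrane site index vectors
#' @export
groupSpec <- function(soluteIdx, groups, cap = Inf) {
  new("GroupSpec", soluteIdx = as.integer(soluteIdx),
      groups = lapply(groups, as.integer), cap = cap)
}

#' Minimum-distance features of one frame
#'
#' Entry (b, g) is the minimum over the sites of group g of the
#' minimum-image distance to solute bead b. The smooth variant
#' (`beta` finite) uses the mean-normalized soft minimum
#' -(1/beta) log mean(exp(-beta*d)), which bounds the hard minimum from
#' above and converges to it as `beta -> Inf`; it is the differentiable
#' form used when the CV must supply bias forces.
#'
#' @param frame N x 3 coordinate matrix
#' @param groups a [GroupSpec-class]
#' @param box,periodic box lengths and periodicity flags
#' @param beta softmin sharpness (1/nm); `Inf` = hard minimum
#' @return named numeric vector of length B*G, names `min_d.<b>.<group>`
#' @export
minDistanceFeatures <- function(frame, groups, box, periodic, beta = Inf) {
  B <- length(groups@soluteIdx)
  G <- length(groups@groups)
  if (any(vapply(groups@groups, length, 1L) == 0))
    stop("empty descriptor group: ",
         names(groups@groups)[vapply(groups@groups, length, 1L) == 0][1])
  sol <- frame[groups@soluteIdx, , drop = FALSE]
  out <- matrix(NA_real_, B, G)
  for (g in seq_len(G)) {
    d <- .groupDistances(sol, frame[groups@groups[[g]], , drop = FALSE],
                         box, periodic)                       # B x |g|
    if (is.finite(groups@cap)) d <- pmin(d, groups@cap)
    dm <- .rowMins(d)
    out[, g] <- if (is.finite(beta))
      dm - log(rowMeans(exp(-beta * (d - dm)))) / beta else dm
  }
  v <- as.vector(t(out))     # bead-major: (b1,g1..gG, b2,g1..gG, ...)
  names(v) <- as.vector(t(outer(seq_len(B), names(groups@groups),
                                function(b, g) paste0("min_d.b", b, ".", g))))
  v
}

#' @noRd
.rowMins <- function(d) {
  m <- d[, 1]
  for (j in seq_len(ncol(d))[-1]) m <- pmin(m, d[, j])
  m
}

## minimum-image distance matrix between solute beads and one site group
#' @noRd
.groupDistances <- function(sol, sites, box, periodic) {
  d2 <- 0
  for (ax in seq_len(ncol(sol))) {
    dd <- outer(sol[, ax], sites[, ax], "-")
    if (periodic[ax]) dd <- minImage(dd, box[ax])
    d2 <- d2 + dd^2
  }
  sqrt(d2)
}

## Fused chain rule for CV bias forces: given per-feature coefficients
## (d cv / d feature, bead-major order matching minDistanceFeatures),
## accumulate sum_k coef_k * d feature_k / d coords in one pass. Softmin
## only (the hard min is not differentiable where it matters).
#' @noRd
.minDistanceChainGrad <- function(frame, groups, box, periodic, beta, coefs) {
  stopifnot(is.finite(beta))
  B <- length(groups@soluteIdx)
  G <- length(groups@groups)
  cf <- matrix(coefs, G, B)     # coefs are bead-major
  grad <- matrix(0, nrow(frame), ncol(frame))
  sol <- frame[groups@soluteIdx, , drop = FALSE]
  for (g in seq_len(G)) {
    ig <- groups@groups[[g]]
    sites <- frame[ig, , drop = FALSE]
    diffs <- vector("list", ncol(frame))
    d2 <- 0
    for (ax in seq_len(ncol(frame))) {
      dd <- outer(sol[, ax], sites[, ax], "-")    # bead - site
      if (periodic[ax]) dd <- minImage(dd, box[ax])
      diffs[[ax]] <- dd
      d2 <- d2 + dd^2
    }
    d <- sqrt(d2)
    capped <- if (is.finite(groups@cap)) d >= groups@cap else FALSE
    if (is.finite(groups@cap)) d <- pmin(d, groups@cap)
    dm <- .rowMins(d)
    p <- exp(-beta * (d - dm))
    p <- p / rowSums(p)                            # softmin weights, B x |g|
    contrib <- p * cf[g, ] / pmax(d, 1e-12)
    contrib[capped] <- 0
    for (ax in seq_len(ncol(frame))) {
      cA <- contrib * diffs[[ax]]
      grad[groups@soluteIdx, ax] <- grad[groups@soluteIdx, ax] + rowSums(cA)
      grad[ig, ax] <- grad[ig, ax] - colSums(cA)
    }
  }
  grad
}

#' Signed z-distance between solute and membrane centers of mass
#'
#' Perpendicular (z) separation of the solute center of mass from the
#' membrane center of mass; positive on the solute's starting (water) side.
#' z is aperiodic in all toy systems.
#'
#' @param frame N x 3 coordinate matrix
#' @param soluteIdx,membraneIdx index sets (non-empty)
#' @param masses optional per-particle masses (geometric centers otherwise)
#' @return signed separation (nm)
#' @export
zDistance <- function(frame, soluteIdx, membraneIdx, masses = NULL) {
  stopifnot(length(soluteIdx) > 0, length(membraneIdx) > 0)
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  zc <- function(idx) sum(masses[idx] * frame[idx, 3]) / sum(masses[idx])
  zc(soluteIdx) - zc(membraneIdx)
}

#' Z-component of the solute dipole moment
#'
#' Sum of q_i (z_i - z_COM) over the solute beads, with a geometric center
#' of mass; reported in e*nm.
#'
#' @param frame N x 3 coordinate matrix
#' @param soluteIdx solute bead indices
#' @param charges charge per solute bead (e)
#' @return dipole z-component (e*nm)
#' @export
zDipole <- function(frame, soluteIdx, charges) {
  if (length(charges) != length(soluteIdx))
    stop("need one charge per solute bead (got ", length(charges), " for ",
         length(soluteIdx), " beads)")
  z <- frame[soluteIdx, 3]
  sum(charges * (z - mean(z)))
}

#' Build the descriptor matrix of a trajectory
#'
#' Evaluates the minimum-distance features on every post-discard frame (in
#' time order) and attaches the physical validation coordinates (z-distance,
#' z-dipole), ground-truth basin labels, and per-frame log-weights from the
#' recorded bias.
#'
#' @param traj a mini-bilayer [Trajectory-class]
#' @param groups a [GroupSpec-class]; defaults to [defaultGroupSpec()]
#' @param discard initial time to drop (ps)
#' @param beta softmin sharpness; `Inf` (hard minimum) for training data
#' @return a [DescriptorSet-class] with d = B*G columns
#' @export
buildDescriptorMatrix <- function(traj, groups = NULL, discard = 0,
                                  beta = Inf) {
  sys <- traj@system
  if (is.null(groups)) groups <- defaultGroupSpec(sys)
  keep <- which(traj@times > discard)
  if (!length(keep))
    stop("no frames remain after discarding the first ", discard, " ps")
  B <- length(groups@soluteIdx)
  G <- length(groups@groups)
  vals <- matrix(NA_real_, length(keep), B * G)
  zd <- zp <- numeric(length(keep))
  for (r in seq_along(keep)) {
    fr <- traj@frames[keep[r], , ]
    f <- minDistanceFeatures(fr, groups, sys@box, sys@periodic, beta = beta)
    if (r == 1) colnames(vals) <- names(f)
    vals[r, ] <- f
    zd[r] <- zDistance(fr, sys@soluteIdx, sys@membraneIdx, sys@masses)
    zp[r] <- zDipole(fr, sys@soluteIdx, sys@charges)
  }
  lw <- traj@bias[keep] / .kBT(traj@temperature)
  aux <- data.frame(time = traj@times[keep], z_dist = zd, z_dipole = zp,
                    logweight = lw,
                    label = as.character(basinLabels(traj))[keep],
                    walker = traj@walker)
  new("DescriptorSet", values = vals, aux = aux,
      nBeads = as.integer(B), nGroups = as.integer(G))
}

#' Concatenate descriptor sets from several walkers
#'
#' Rows stay in (walker, time) order; the walker id is preserved so that
#' time-lagged pairs never cross walker boundaries.
#'
#' @param sets list of [DescriptorSet-class] objects with identical columns
#' @return a single [DescriptorSet-class]
#' @export
bindDescriptors <- function(sets) {
  stopifnot(length(sets) >= 1)
  v <- do.call(rbind, lapply(sets, function(s) s@values))
  aux <- do.call(rbind, lapply(sets, function(s) s@aux))
  new("DescriptorSet", values = v, aux = aux,
      nBeads = sets[[1]]@nBeads, nGroups = sets[[1]]@nGroups)
}
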