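#' Toy-potential constructors
#'
#' @description
#' `doubleWellSpec()` builds a 1D quartic double well,
#' U(x) = h*((x/a)^2 - 1)^2 - (deltaG/2)*tanh(x/(0.25 a)),
#' with barrier `h` at x = 0, minima near +/- `a`, and a tanh tilt that
#' offsets the basin depths by `deltaG` (negative = left/"membrane" basin
#' favored) while leaving the curvatures equal, so the programmed `deltaG` is
#' also the basin free-energy difference to high accuracy.
#'
#' `insertionSpec()` embeds the same well along a slow direction
#' s = x + coupling*y with a harmonic orthogonal coordinate
#' (kOrth/2)*y^2. `x` plays the role of the physical insertion depth
#' (z-distance analogue); with `coupling > 0` the free-energy barrier along
#' bare `x` is strictly below the barrier along `s`, emulating the
#' transition-state overlap seen when projecting a membrane-entry process
#' onto the z-distance alone.
#'
#' `miniBilayerSpec()` describes the particle-based stand-in for a
#' coarse-grained membrane simulation: `nLipidTypes * sitesPerType` typed
#' lipid sites harmonically tethered to a symmetric slab lattice about
#' z = 0, plus a charged solute chain of `soluteBeads` beads started in the
#' water region. Solute beads feel a slab attraction, an interfacial
#' barrier, Gaussian pair wells to the lipid sites, and a soft confining
#' wall near the box edge; x and y are periodic, z is not.
#'
#' @param barrier barrier height h (kJ/mol), must be > 0
#' @param a basin position (nm)
#' @param deltaG programmed basin depth difference, membrane minus water
#'   (kJ/mol)
#' @param coupling dimensionless mixing of the orthogonal coordinate into
#'   the slow direction (0 = the x projection is exact)
#' @param kOrth orthogonal restoring constant (kJ/mol/nm^2)
#' @param nLipidTypes number of distinct descriptor-eligible lipid site
#'   groups G (DOPC/SM analogues)
#' @param nExcludedTypes extra site types present in the membrane but
#'   excluded from descriptor groups (CHOL/GM1 analogues)
#' @param sitesPerType lipid sites per group
#' @param soluteBeads solute chain length B (>= 2)
#' @param slabHalfWidth membrane half-thickness w (nm)
#' @param box box lengths (nm), z aperiodic
#' @param charges per-bead charges (e); default: a -1 "sulfate" head and a
#'   +1,+1,+1 "polyamine" tail
#' @param epsMembrane per-bead slab attraction depth (kJ/mol)
#' @param interfaceBarrier per-bead interfacial barrier height (kJ/mol)
#' @param epsPair pair-well depths per lipid type (kJ/mol, recycled to G)
#' @param pairRange Gaussian pair-well range (nm)
#' @param kTether,kBond,r0Bond lipid tether and solute bond parameters
#' @return a validated [PotentialSpec-class]
#' @examples
#' doubleWellSpec(barrier = 10, deltaG = -10)
#' @export
doubleWellSpec <- function(barrier = 10, a = 1, deltaG = 0) {
  new("PotentialSpec", kind = "double_well_1d",
      params = list(barrier = barrier, a = a, deltaG = deltaG,
                    domain = list(x = c(-3 * a, 3 * a))))
}

#' @rdname doubleWellSpec
#' @param k harmonic force constant (kJ/mol/nm^2)
#' @export
harmonicSpec <- function(k = 10) {
  dom <- 6 * sqrt(.kBT(500) / k)
  new("PotentialSpec", kind = "harmonic_1d",
      params = list(k = k, barrier = 1, domain = list(x = c(-dom, dom))))
}

#' @rdname doubleWellSpec
#' @export
insertionSpec <- function(barrier = 10, a = 1, deltaG = 0, coupling = 0,
                          kOrth = 20) {
  yr <- sqrt(36 * .kBT(500) / kOrth) + abs(coupling) * 1.5 * a
  new("PotentialSpec", kind = "insertion_2d",
      params = list(barrier = barrier, a = a, deltaG = deltaG,
                    coupling = coupling, kOrth = kOrth,
                    domain = list(x = c(-3 * a, 3 * a) + c(-1, 1) * abs(coupling) * yr,
                                  y = c(-yr, yr))))
}

#' @rdname doubleWellSpec
#' @export
miniBilayerSpec <- function(nLipidTypes = 12L, sitesPerType = 4L,
                            nExcludedTypes = 4L,
                            soluteBeads = 15L, slabHalfWidth = 1.5,
                            box = c(4, 4, 12), charges = NULL,
                            epsMembrane = 0.8, interfaceBarrier = 0.5,
                            epsPair = c(1.2, 0.6), pairRange = 0.5,
                            kTether = 100, kBond = 1000, r0Bond = 0.35) {
  B <- as.integer(soluteBeads)
  if (is.null(charges)) {
    charges <- numeric(B)
    charges[1] <- -1
    charges[max(1, B - 2):B] <- 1
  }
  nT <- as.integer(nLipidTypes) + as.integer(nExcludedTypes)
  new("PotentialSpec", kind = "mini_bilayer",
      params = list(nLipidTypes = as.integer(nLipidTypes),
                    nExcludedTypes = as.integer(nExcludedTypes),
                    sitesPerType = as.integer(sitesPerType),
                    soluteBeads = B, slabHalfWidth = slabHalfWidth,
                    box = box, charges = charges,
                    epsMembrane = epsMembrane,
                    interfaceBarrier = interfaceBarrier,
                    epsPair = rep_len(epsPair, nT),
                    pairRange = pairRange, kTether = kTether,
                    kBond = kBond, r0Bond = r0Bond,
                    barrier = interfaceBarrier * B))
}

## Conservative estimate of the stiffest curvature (kJ/mol/nm^2) in a spec,
## used by the integrator's dt stability check.
#' @noRd
.stiffness <- function(spec) {
  p <- spec@params
  switch(spec@kind,
    harmonic_1d = p$k,
    double_well_1d = 8 * p$barrier / p$a^2 + 8 * abs(p$deltaG) / p$a^2,
    insertion_2d = max(8 * p$barrier / p$a^2 * (1 + p$coupling^2), p$kOrth),
    mini_bilayer = max(p$kTether, p$kBond,
                       (p$epsMembrane + p$interfaceBarrier) / 0.25^2 * 4,
                       max(p$epsPair) / p$pairRange^2 * 4)
  )
}
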