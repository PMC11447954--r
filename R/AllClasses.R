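#' @import methods
NULL

#' Specification of a toy model potential
#'
#' Three kinds are supported: `"double_well_1d"` (a quartic double well with a
#' tanh tilt that offsets the two basin depths without changing their
#' curvature), `"insertion_2d"` (the double well along a slow direction
#' s = x + coupling*y with a harmonic orthogonal coordinate; the coupling
#' makes the barrier along the bare x projection lower than along s, the
#' hallmark of a poor physical CV), and `"mini_bilayer"` (typed lipid sites
#' harmonically tethered to a slab lattice about z = 0 plus a charged solute
#' bead chain started in the water region).
#'
#' All parameters are stored in `params` (nm, kJ/mol, e). Use the
#' constructors [doubleWellSpec()], [insertionSpec()] and [miniBilayerSpec()].
#'
#' @slot kind one of `"double_well_1d"`, `"insertion_2d"`, `"mini_bilayer"`
#' @slot params named list of parameters; see constructors
#' @export
setClass("PotentialSpec",
  slots = c(kind = "character", params = "list"))

setValidity("PotentialSpec", function(object) {
  p <- object@params
  if (!object@kind %in% c("harmonic_1d", "double_well_1d", "insertion_2d", "mini_bilayer"))
    return(sprintf("unknown potential kind '%s'", object@kind))
  if (!is.null(p$barrier) && p$barrier <= 0)
    return("barrier height must be > 0")
  if (object@kind == "mini_bilayer") {
    if (p$soluteBeads < 2) return("solute bead count must be >= 2")
    if (any(p$box[3] <= 2 * p$slabHalfWidth))
      return("box z-length must exceed twice the slab width")
    if (p$pairRange >= min(p$box[1:2]) / 2)
      return("pair-well range must be below half the shortest box length")
    if (length(p$charges) != p$soluteBeads)
      return("one charge per solute bead required")
  }
  TRUE
})

#' A toy particle system with analytic energies and forces
#'
#' Built by [buildSystem()]. Coordinates are an N x nDim matrix; for the
#' analytic toys N = 1 and nDim is 1 or 2, for the mini-bilayer nDim = 3 with
#' x,y periodic and z aperiodic.
#'
#' @slot spec the generating [PotentialSpec-class]
#' @slot coords0 initial coordinates, N x nDim (nm)
#' @slot box box lengths per axis (nm); `Inf` on aperiodic axes
#' @slot periodic logical per axis
#' @slot masses per-particle masses (amu-like; toys use 1)
#' @slot soluteIdx,membraneIdx particle index sets (mini-bilayer only)
#' @slot charges solute bead charges (e)
#' @slot siteTypes membrane site type label per membrane particle
#' @slot tether lattice tether positions for membrane sites (matrix)
#' @slot seed build seed
#' @export
setClass("ToySystem",
  slots = c(spec = "PotentialSpec", coords0 = "matrix", box = "numeric",
            periodic = "logical", masses = "numeric",
            soluteIdx = "integer", membraneIdx = "integer",
            charges = "numeric", siteTypes = "character",
            tether = "matrix", seed = "integer"))

#' A sampled trajectory with per-frame energy and bias records
#'
#' @slot frames array T x N x nDim of positions (nm), wrapped into the box on
#'   periodic axes
#' @slot times frame times (ps)
#' @slot potential per-frame potential energy (kJ/mol)
#' @slot bias per-frame total bias energy (kJ/mol); zeros for unbiased runs
#' @slot cv per-frame value of the biased CV (NA when not applicable)
#' @slot temperature thermostat temperature (K)
#' @slot system the [ToySystem-class] that produced the run
#' @slot seed RNG seed of the run
#' @slot walker walker index (shared-bias runs)
#' @export
setClass("Trajectory",
  slots = c(frames = "array", times = "numeric", potential = "numeric",
            bias = "numeric", cv = "numeric", temperature = "numeric",
            system = "ToySystem", seed = "integer", walker = "integer"))

setValidity("Trajectory", function(object) {
  T <- dim(object@frames)[1]
  if (T < 1) return("at least one frame required")
  if (length(object@bias) != T) return("bias record length must match frames")
  if (length(object@potential) != T) return("potential record length must match frames")
  if (!all(is.finite(object@potential)) || !all(is.finite(object@bias)))
    return("energies must be finite")
  box <- object@system@box
  per <- object@system@periodic
  for (ax in which(per)) {
    z <- object@frames[, , ax, drop = FALSE]
    if (any(z < -1e-9 | z > box[ax] + 1e-9))
      return(sprintf("positions not wrapped into box on periodic axis %d", ax))
  }
  TRUE
})

#' Descriptor group specification
#'
#' Names which particles form the solute and which membrane sites belong to
#' each group of identical lipid beads. One group per (lipid type x bead
#' type); groups must be disjoint and non-empty. An optional distance `cap`
#' saturates large separations (off by default, `Inf`).
#'
#' @slot soluteIdx solute bead indices
#' @slot groups named list of membrane site index vectors
#' @slot cap saturation distance (nm), `Inf` = no cap
#' @export
setClass("GroupSpec",
  slots = c(soluteIdx = "integer", groups = "list", cap = "numeric"))

setValidity("GroupSpec", function(object) {
  if (!length(object@soluteIdx)) return("solute index set empty")
  if (!length(object@groups)) return("no descriptor groups")
  if (is.null(names(object@groups)) || anyDuplicated(names(object@groups)))
    return("groups must be uniquely named")
  if (any(vapply(object@groups, length, 1L) == 0))
    return(sprintf("empty group: %s",
                   names(object@groups)[vapply(object@groups, length, 1L) == 0][1]))
  idx <- unlist(object@groups)
  if (anyDuplicated(idx)) return("descriptor groups must be disjoint")
  TRUE
})

#' Minimum-distance descriptor matrix
#'
#' Rows are post-discard frames in time order; columns are
#' `min_d.<bead>.<group>` features (nm) with d = B x G. Auxiliary physical
#' validation coordinates (z-distance to the membrane center, z-component of
#' the solute dipole) and per-frame log-weights from the bias record travel
#' in `aux`.
#'
#' @slot values T x d feature matrix
#' @slot aux data.frame with columns time, z_dist, z_dipole, logweight, label
#' @slot nBeads,nGroups factorization of d
#' @export
setClass("DescriptorSet",
  slots = c(values = "matrix", aux = "data.frame",
            nBeads = "integer", nGroups = "integer"))

setValidity("DescriptorSet", function(object) {
  if (ncol(object@values) != object@nBeads * object@nGroups)
    return("d must equal nBeads * nGroups")
  if (anyDuplicated(colnames(object@values))) return("column names must be unique")
  isMinD <- grepl("^min_d", colnames(object@values) %||% "")
  if (any(object@values[, isMinD, drop = FALSE] < -1e-12))
    return("minimum distances must be >= 0")
  if (nrow(object@aux) != nrow(object@values)) return("aux rows must match values")
  TRUE
})

#' Weighted time-lagged covariance pair
#'
#' @slot C0 instantaneous covariance (symmetric PSD)
#' @slot Ct lagged covariance, symmetrized as (Ct + t(Ct))/2
#' @slot means weighted feature means
#' @slot lag lag in `lagUnit`
#' @slot lagUnit `"frames"` or `"rescaled"` (cumulative-weight clock)
#' @slot ess effective sample size of the pair weights
#' @slot nPairs number of lagged pairs used
#' @slot rankDeficient flagged when fewer than d+1 effective pairs exist
#' @export
setClass("LaggedCovariances",
  slots = c(C0 = "matrix", Ct = "matrix", means = "numeric", lag = "numeric",
            lagUnit = "character", ess = "numeric", nPairs = "integer",
            rankDeficient = "logical"))

#' Linear TICA model
#'
#' @slot evals eigenvalues, sorted descending, clipped to <= 1
#' @slot evecs d x k eigenvectors, C0-orthonormal
#' @slot lag,lagUnit lag of the underlying covariances
#' @slot timescales implied timescales -lag/log(lambda); `Inf`/`NaN`
#'   sentinels for unit / non-positive eigenvalues (see `flagged`)
#' @slot flagged logical per mode: sentinel timescale
#' @slot clipped number of eigenvalues clipped at 1
#' @slot means feature means used for centering
#' @export
setClass("TicaModel",
  slots = c(evals = "numeric", evecs = "matrix", lag = "numeric",
            lagUnit = "character", timescales = "numeric",
            flagged = "logical", clipped = "integer", means = "numeric"))

setValidity("TicaModel", function(object) {
  if (is.unsorted(rev(object@evals), strictly = FALSE)) {
    if (any(diff(object@evals) > 1e-10)) return("eigenvalues must be sorted descending")
  }
  if (any(object@evals > 1 + 1e-9)) return("eigenvalues must be clipped to <= 1")
  TRUE
})

#' Deep-TICA collective-variable model
#'
#' A per-feature standardizer, a feed-forward tanh network
#' (widths d, 128, 64, nOut), a TICA projection on the network outputs and an
#' affine scaling that maps the training-set CV range onto [-1, 1] with the
#' water basin toward +1.
#'
#' @slot std standardizer: means, sds, kept-column map
#' @slot weights list W1,b1,W2,b2,W3,b3
#' @slot arch layer widths, c(d, 128, 64, nOut)
#' @slot proj TICA combination of network outputs defining the CV
#' @slot scaleA,scaleB affine scaling cv = scaleA * raw + scaleB
#' @slot evals TICA eigenvalues of the trained outputs
#' @slot lag,lagUnit training lag
#' @slot featureNames retained descriptor names (input contract)
#' @slot trainLog per-epoch train/validation loss and eigenvalues
#' @slot seed training seed
#' @export
setClass("DeepTicaModel",
  slots = c(std = "list", weights = "list", arch = "integer",
            proj = "numeric", scaleA = "numeric", scaleB = "numeric",
            evals = "numeric", lag = "numeric", lagUnit = "character",
            featureNames = "character", trainLog = "data.frame",
            seed = "integer"))

#' OPES MetaD bias state (well-tempered target along one CV)
#'
#' Compressed kernel list with running normalization. The bias is
#' V(s) = (1 - 1/gamma) * kBT * log(eps + (1 - eps) * min(p(s)/pmax, 1)),
#' with eps = exp(-barrier / ((1 - 1/gamma) kBT)), which confines the bias
#' range to [-barrier, 0] exactly.
#'
#' @slot kernels matrix with columns center, sigma, height
#' @slot gamma bias factor (default barrier / kBT)
#' @slot eps regularizer from the barrier parameter
#' @slot barrier maximum barrier the bias may overcome (kJ/mol; default 60)
#' @slot sigma0 initial bandwidth (unbiased CV standard deviation)
#' @slot sigmaMin bandwidth floor (CV units; default 0.028)
#' @slot stride deposition stride in integrator steps (default 500)
#' @slot mergeThreshold kernel-merge distance in sigma units
#' @slot pmax running max kernel density over kernel centers
#' @slot Z running mean kernel density over kernel centers
#' @slot sumW,sumW2 accumulated deposition weights (for n_eff)
#' @slot lastSigma last deposited bandwidth (nonincreasing sequence)
#' @slot nDeposits deposit counter
#' @export
setClass("OpesState",
  slots = c(kernels = "matrix", gamma = "numeric", eps = "numeric",
            barrier = "numeric", sigma0 = "numeric", sigmaMin = "numeric",
            stride = "integer", mergeThreshold = "numeric", pmax = "numeric",
            Z = "numeric", sumW = "numeric", sumW2 = "numeric",
            lastSigma = "numeric", nDeposits = "integer"))

setValidity("OpesState", function(object) {
  if (object@eps <= 0) return("eps must be > 0")
  if (nrow(object@kernels)) {
    if (any(object@kernels[, "sigma"] < object@sigmaMin - 1e-12))
      return("kernel bandwidths must respect the floor")
    if (any(object@kernels[, "height"] <= 0)) return("kernel heights must be > 0")
    if (object@Z <= 0) return("normalization must be > 0")
  }
  TRUE
})

#' OPES expanded (multithermal) bias state
#'
#' Inverse-temperature grid spanning a temperature range (default
#' 270-500 K) with running free-energy shift estimates c_j, sampled from a
#' simulation temperature inside the range.
#'
#' @slot betas inverse-temperature grid (1/kJ/mol), sorted
#' @slot beta simulation inverse temperature
#' @slot cj running shift estimates (dimensionless)
#' @slot logSumW,logTerms log-domain accumulators behind cj
#' @slot stride update stride in integrator steps
#' @slot nSamples samples absorbed
#' @export
setClass("ExpandedState",
  slots = c(betas = "numeric", beta = "numeric", cj = "numeric",
            logSumW = "numeric", logTerms = "numeric", stride = "integer",
            nSamples = "integer"))

setValidity("ExpandedState", function(object) {
  if (is.unsorted(object@betas)) return("beta grid must be sorted")
  if (object@beta > max(object@betas) + 1e-12 ||
      object@beta < min(object@betas) - 1e-12)
    return("simulation temperature must lie inside the expanded range")
  if (any(!is.finite(object@cj))) return("c_j must be finite")
  TRUE
})

#' Gridded free-energy surface with uncertainty
#'
#' @slot grid list of axis bin centers (1 or 2 axes)
#' @slot values free energy (kJ/mol), min-shifted to 0; `NA` marks
#'   never-visited bins
#' @slot se per-bin standard error (kJ/mol) from block bootstrap
#' @slot ess effective sample size per bin
#' @slot cvNames,cvUnits axis labels
#' @slot temperature temperature of the estimate (K)
#' @slot metadata free-form list (bootstrap replicates, provenance)
#' @export
setClass("FreeEnergySurface",
  slots = c(grid = "list", values = "array", se = "array", ess = "array",
            cvNames = "character", cvUnits = "character",
            temperature = "numeric", metadata = "list"))

setValidity("FreeEnergySurface", function(object) {
  v <- object@values
  if (all(is.na(v))) return("no occupied bins")
  if (abs(min(v, na.rm = TRUE)) > 1e-8) return("free energy must be min-shifted to 0")
  if (any(object@se < 0, na.rm = TRUE)) return("uncertainties must be >= 0")
  TRUE
})

#' Basin free-energy analysis result
#'
#' @slot dG basin free-energy difference B - A (kJ/mol)
#' @slot dGse standard error of dG
#' @slot barrier entry barrier dG-dagger, F(saddle) - F(min A) (kJ/mol)
#' @slot barrierLocation CV value at the saddle
#' @slot minima CV locations of the two basin minima
#' @slot ranges basin definitions used
#' @slot flags e.g. "monotone" when no saddle exists (barrier reported 0)
#' @slot method "integral" or "minima"
#' @export
setClass("BasinResult",
  slots = c(dG = "numeric", dGse = "numeric", barrier = "numeric",
            barrierLocation = "numeric", minima = "numeric", ranges = "list",
            flags = "character", method = "character"))

setValidity("BasinResult", function(object) {
  if (object@barrier < -1e-9) return("barrier must be >= 0")
  if (object@dGse < 0) return("SE must be >= 0")
  TRUE
})

#' Saturation-binding fit result
#'
#' Hyperbolic saturation model F(L) = F0 + A * L / (K_D + L) fitted to a
#' normalized fluorescence titration.
#'
#' @slot F0 fluorescence at zero vesicle concentration (%)
#' @slot A emission difference between unbound and bound states (%)
#' @slot kd dissociation constant (mg/mL total lipid)
#' @slot kdSe standard error of kd from the fit covariance
#' @slot dG binding free energy (kJ/mol), filled by [kdToDg()]
#' @slot dGse propagated error on dG
#' @slot diagnostics residual SS, convergence flag, identifiability flag
#' @export
setClass("BindingFit",
  slots = c(F0 = "numeric", A = "numeric", kd = "numeric", kdSe = "numeric",
            dG = "numeric", dGse = "numeric", diagnostics = "list"))

setValidity("BindingFit", function(object) {
  if (isTRUE(object@diagnostics$identifiable) && object@kd <= 0)
    return("K_D must be > 0")
  TRUE
})

#' End-to-end protocol configuration
#'
#' Two-phase run plan: multithermal exploration, descriptor featurization,
#' Deep-TICA training, CV-biased OPES MetaD with shared-bias walkers, FES /
#' basin analysis, and optional binding comparison.
#'
#' @slot spec the toy system specification
#' @slot phase1,phase2 lists: steps, walkers, stride, dt, temperature
#' @slot discardFrac fraction of phase-1 frames discarded before training
#' @slot train Deep-TICA training settings (see [trainConfig()])
#' @slot fes list: grid size, basin ranges
#' @slot binding synthetic binding parameters or a CSV path
#' @slot seed global seed, fanned out per stage
#' @export
setClass("ProtocolConfig",
  slots = c(spec = "PotentialSpec", phase1 = "list", phase2 = "list",
            discardFrac = "numeric", train = "list", fes = "list",
            binding = "list", seed = "integer"))

setValidity("ProtocolConfig", function(object) {
  if (object@phase1$walkers < 1 || object@phase2$walkers < 1)
    return("walker counts must be >= 1")
  if (object@discardFrac < 0 || object@discardFrac >= 1)
    return("discard fraction must be in [0, 1)")
  TRUE
})
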