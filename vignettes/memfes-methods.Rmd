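---
title: "Methods: enhanced sampling and learned CVs for membrane insertion"
author: "memfes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhanced sampling and learned CVs for membrane insertion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(memfes)
```

# The problem

Estimating the free energy of solute insertion into a lipid membrane from
molecular dynamics is hard for two reasons: insertion events are rare on
simulation timescales, and the obvious reaction coordinate — the distance
`z` between the solute's center of mass and the membrane center — hides
slow orthogonal degrees of freedom (solute orientation, solute–lipid
contacts, lipid rearrangements). Biasing along `z` alone therefore
converges slowly and systematically underestimates the entry barrier,
because configurations belonging to the transition-state ensemble project
onto the same `z` values as basin configurations.

`memfes` implements, at desk scale, a protocol that addresses both
problems: (1) an exploration phase samples a *multithermal* ensemble
(270–500 K) so that insertion/exit transitions occur without choosing any
CV a priori; (2) a nonlinear slow-mode analysis (Deep-TICA) trained on
minimum-distance descriptors of those transitions yields a one-dimensional
collective variable that separates the water and membrane states; (3) a
second phase biases that CV with OPES MetaD, using several walkers sharing
one bias; (4) reweighting gives free-energy surfaces along any coordinate,
basin free-energy differences ΔG and entry barriers ΔG‡ with
block-bootstrap errors; (5) an independent experimental-side module fits
saturation-binding titrations for K_D and converts them to ΔG for direct
comparison.

All dynamics run on toy systems with analytically known thermodynamics, so
every estimator in the package can be validated against deterministic
quadrature rather than against other samplers.

# The toy world

Three model potentials are provided (units: nm, ps, kJ/mol, K, e;
`kBoltz = 0.0083144621` kJ/mol/K).

**Tilted double well** (`doubleWellSpec`): U(x) = h((x/a)² − 1)² −
(ΔG/2)·tanh(x/(0.25a)). The tanh tilt offsets the basin *depths* by ΔG
while leaving both curvatures equal, so the programmed ΔG is also the
basin free-energy difference to better than 0.05 kJ/mol at the default
temperatures. This is the workhorse oracle for bias-recovery tests.

**2D insertion model** (`insertionSpec`): the same well along a slow
direction s = x + c·y plus a harmonic restoring force (k_o/2)y². `x`
plays the role of the physical z-distance and `y` an orientation-like
coordinate. For c > 0, integrating out `y` at fixed `x` lets the system
relax around the barrier, so the free-energy barrier along `x` is
strictly below the barrier along `s` — the projection artifact the
learned CV is supposed to avoid — while the basin ΔG is identical along
both projections (path independence). Both facts are computable exactly
by 2D quadrature (`analyticFes`), which is what the tests assert.

**Mini-bilayer** (`miniBilayerSpec`): a particle-based stand-in for a
coarse-grained membrane simulation. Typed lipid sites (default 12
descriptor-eligible types × 4 sites, plus 4 excluded CHOL/GM1-analogue
types) are harmonically tethered to a symmetric slab lattice about z = 0
— tethered, not frozen, so lipid-arrangement degrees of freedom exist for
the CV to learn. A charged solute chain (default B = 15 beads, a −1
"sulfate" head and a +1,+1,+1 "polyamine" tail) starts in the water
region and feels a smooth slab attraction, an interfacial barrier,
Gaussian pair wells to the lipid sites and a soft confining wall; x,y are
periodic, z is not. Ground truth for CV-quality tests is |z_COM| against
the slab half-width. With B = 15 and 12 groups the descriptor stage
yields 15 × 12 = 180 features (a 14-bead solute gives 168), matching the
dimensionalities of the two aminosterol systems the protocol was designed
around.

What the mini-bilayer emulates: the statistical structure of the learning
problem — many weakly informative minimum-distance features, two
metastable states, slow orthogonal modes, biased (multithermal) training
data. What it does not emulate: real lipid chemistry, electrostatics,
pressure coupling, microsecond timescales. A green test therefore
establishes correctness of the estimators and the learning machinery, not
of any force field.

# Dynamics

`runLangevin` integrates NVT Langevin dynamics with the BAOAB splitting
(friction default 1/ps), which has the best configurational accuracy per
step among the common Langevin splittings. A time step is rejected up
front if dt·ω > 1 for the stiffest curvature ω² in the spec. Thermostat
and barostat machinery of production MD codes is deliberately out of
scope.

# Descriptors

`minDistanceFeatures` computes, per frame, the minimum over each group of
identical lipid sites of the minimum-image distance to each solute bead.
Training data use the hard minimum. When the CV must supply continuous
bias forces, a smooth minimum is used instead:
softmin_β(d) = −(1/β)·log(mean exp(−β d)) with β = 50/nm. This
mean-normalized form lies *above* the hard minimum and converges to it
monotonically as β → ∞ (the plain log-sum-exp form lies below, which
would violate the bound the tests assert). CHOL/GM1-analogue sites are
excluded from the descriptor groups, mirroring the restriction of the
descriptor set to the two phospholipid species. An optional saturation
cap on large distances exists but is off by default. The physical
validation coordinates carried alongside are the signed z-distance
between solute and membrane centers of mass and the z-component of the
solute dipole Σqᵢ(zᵢ − z_COM).

# TICA and Deep-TICA

`laggedCovariances` builds mean-free, symmetrized (reversible) estimators
C0 and Cτ. For biased trajectories, frame pairs are selected on the
*rescaled-time* clock accumulated from w = exp(V/k_BT), with pair weight
√(wᵢwⱼ); this unbiases the slow-mode estimate without discarding data.
Pairs never cross walker boundaries. `solveTica` solves
Cτ v = λ (C0 + εI) v by symmetric whitening, with ε defaulting to
10⁻⁶·tr(C0)/d to stabilize near-duplicate distance features; eigenvalues
above 1 are clipped and logged, eigenvectors are renormalized to exact
C0-orthonormality, and implied timescales −τ/log λ flag (rather than
drop) unit or non-positive eigenvalues.

Deep-TICA replaces the linear feature map with a feed-forward network
(widths d–128–64–4, tanh; inputs standardized to zero mean and unit
variance with zero-variance columns dropped and logged). The training
loss is −Σᵢ λᵢ² over the top four eigenvalues of the TICA problem solved
on the network outputs; gradients flow through the generalized
eigenproblem via dλ = vᵀ(dCτ − λ dC0)v. Optimization is full-batch Adam
(learning rate 10⁻³) with early stopping at patience 10 on the validation
loss of a contiguous 80/20 time-block split (validation last, respecting
temporal correlation). Training is deterministic given the seed.

The exported CV is the leading TICA combination of the four network
outputs, affinely rescaled so the training-set range maps onto [−1, 1];
out-of-range inputs are *not* clipped. Because eigenvectors are
sign-ambiguous, the orientation is fixed deterministically: the training
frames of maximal z-distance (top decile — deep water) must map above the
frames of minimal z-distance, giving the +1 = water / −1 = membrane
convention. (A single-frame anchor proved fragile: one extreme frame of a
saturating CV can sit above the median yet inside the negative cluster.)

**The lag is a scientific input, not a constant.** The reference protocol
quotes a lag of 0.01 without a unit; we expose it in `trainConfig` and
interpret values below 1 as a fraction of the (rescaled) trajectory
length. On the toys, whose hopping times are tens of frames, useful lags
are 10⁻³–10⁻² of the run; the examples and tests pass it explicitly, and
choosing it within an order of magnitude of the slow relaxation time is
the user's responsibility (eigenvalues near 0 or stuck at 1 are the
telltale failure modes).

Models serialize to self-describing JSON at full floating-point precision
with a checksum over the numeric payload; loading verifies both format
version and checksum.

# OPES

**MetaD flavor** (`newOpesState`, `opesBias`, `opesUpdate`): Gaussian
kernels deposited every 500 steps rebuild the CV's marginal probability
p̃(s); each kernel carries the well-tempered weight exp(V/k_BT) of its
deposition point. Bandwidths start from the unbiased CV standard
deviation of a short pre-run, shrink as n_eff^(−1/5), are forced
nonincreasing and floored at 0.028 CV units; kernels closer than one
bandwidth merge moment-preservingly. The bias is

V(s) = (1 − 1/γ)·k_BT·log( ε + (1 − ε)·min(p̃(s)/p_max, 1) ),

with γ = ΔE/k_BT, ε = exp(−ΔE/((1 − 1/γ)k_BT)) and ΔE = 60 kJ/mol the
maximum crossable barrier. Normalizing by the running *maximum* of the
density over kernel centers (rather than its mean Z, which is still
tracked and reported) differs from the bias only by an s-independent
constant at any fixed state — harmless for dynamics and reweighting —
and makes the bias range land in [−ΔE, 0] *exactly*, so the stated
60 kJ/mol cap is a hard invariant rather than an approximation. γ → 1
degenerates to zero bias.

**Expanded (multithermal) flavor**: the bias acts on the potential energy,
V(U) = −k_BT·log[(1/N)·Σⱼ exp(−(βⱼ−β)U + cⱼ)], over N = 64 geometrically
spaced β points spanning 270–500 K (simulation at 310 K). The shifts are
estimated self-consistently as cⱼ = −log⟨exp(−(βⱼ−β)U)⟩ under running
bias-corrected weights, via overflow-guarded log-sum-exp accumulators;
with this sign convention a constant energy stream drives V to exactly
zero, and a single grid point at the simulation temperature gives V ≡ 0
identically. Reweighting a multithermal run to any target temperature
uses w ∝ exp(βV + (β − β')U).

**Shared-bias walkers** (`runSharedBias`): replicas propagate
independently between deposition strides; at each stride every surviving
walker's sample is pooled into the one common state in deterministic
(walker, time) order, so all walkers subsequently see the identical bias.
A diverging walker is aborted and logged without stopping the run. With
one walker the driver reproduces the single-walker engine bit for bit.

# Free-energy surfaces and basins

`fesNd` estimates F = −k_BT log of the weighted histogram (optionally
Gaussian-smoothed; default no smoothing in 1D, one bin width in 2D),
min-shifted to zero, with never-visited bins NA. Uncertainties come from
a block bootstrap with walkers as blocks (8 contiguous time blocks when no
walker labels exist); the replicate surfaces are kept so downstream basin
quantities propagate errors consistently. ΔG uses basin-integrated
Boltzmann weights — the thermodynamically meaningful definition, which
reduces to the minima difference for sharp basins (a `minima` mode is
provided for comparison). ΔG‡ is the highest point between the two basin
minima relative to the water-side minimum; a monotone profile reports 0
with an explicit flag. Because the quoted errors on the reference values
do not state their method, both the replica spread (`dGse`) and, for
binding fits, the fit covariance are reported rather than guessed
between.

Two analysis conventions deserve mention. First, path-independence of ΔG
across projections is judged at twice the combined standard error; at one
combined SE a perfect estimator would fail roughly a third of the time.
Second, on a learned CV whose [−1, 1] scaling is pinned by extreme
training frames, the bulk of each basin need not sit near ±1;
`cvBasinRanges` therefore places the basin split at the midpoint of the
label-conditional medians of the training CV instead of using fixed
cutoffs.

# Binding analysis

Titrations are normalized so the no-vesicle point is 100% after blank
subtraction. The saturation model F(L) = F0 + A·L/(K_D + L) — chosen
because the labeled-solute emission *increases* with vesicle
concentration; a sign-flipped variant is selectable — is fitted by
multi-start least squares with a Gauss–Newton polish; K_D's standard
error comes from the fit covariance, and an amplitude indistinguishable
from zero flags K_D as unidentifiable instead of returning it silently.

K_D in mg/mL of total lipid converts to molar through the
mole-fraction-weighted mean lipid molar mass (defaults DOPC 786.1, SM
731.1, CHOL 386.7, GM1 1545.0 g/mol at 59:30:10:1, all overridable),
then ΔG = RT·ln(K_D[M]/1 M). For K_D = 0.013 mg/mL at 298.15 K this
convention gives −27.1 kJ/mol, within the ±0.69 quoted for the published
−27.36; the exact published conversion convention (whole vs
outer-leaflet-accessible lipid, salt mass of the ganglioside) is not
stated, and the ~0.2 kJ/mol residual is documented rather than hidden.
Error propagation is first order: δΔG = RT·δK_D/K_D. The
synthetic-titration generator uses the published design as its stated
world: concentrations 0–1.0 mg/mL, five replicates, homoscedastic
Gaussian noise of 2% on the normalized scale (the published errors are
SEM with n = 5; a simple homoscedastic model matches that reporting
style).

# Protocol orchestration

`runProtocol` chains the stages with one global seed fanned out through a
counter-based splitter, per-stage checkpoints keyed by a config hash
(resume reproduces the uninterrupted report bit for bit), and a JSON
report carrying the eigenvalues, CV diagnostics (ROC area of Deep-TICA 1
against the ground-truth labels, sign-convention check), both FES
projections with ΔG/ΔG‡ and errors, and the computational-vs-experimental
comparison table. The full-protocol defaults (8 walkers per phase, 2·10⁵
then 10⁵ steps) reflect the reference run plan scaled to the toys; the
shipped tests and the acceptance script run deliberately reduced lengths
(stated in their configs) to fit interactive budgets. The package's
interface is R functions plus this vignette; no shell entry point is
shipped.

# Known limitations

- The mini-bilayer is a statistical stand-in; nothing in it is
  quantitative lipid physics, and its ΔG is whatever its parameters give.
- Pure-R dynamics limit runs to ~10⁶ steps per minute on one core for the
  1D/2D toys and ~3·10³ steps per second for the 79-particle
  mini-bilayer; the learned-CV biasing phase costs ~4 ms per step because
  every step featurizes and backpropagates.
- OPES here supports one CV (MetaD flavor) and the multithermal target;
  replica exchange, bias exchange and multidimensional kernels are out of
  scope.
- Training is full-batch; the mini-batch path for very long trajectories
  uses contiguous blocks and is intentionally simple.
- The Monte-Carlo coverage test of the binding fit runs 50 repetitions in
  the suite (200 in exploratory runs) purely for time budget.
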