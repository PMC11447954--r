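# memfes

Desk-scale enhanced sampling and machine-learned collective variables for
solute–membrane insertion free energies.

## The problem

How strongly does an amphipathic solute (the motivating case: cationic
aminosterols binding neuron-like lipid vesicles) partition into a membrane,
and over what barrier does it enter? Direct molecular dynamics rarely sees
an insertion event, and the obvious reaction coordinate — the distance *z*
between the solute and the membrane center — hides slow orthogonal degrees
of freedom (orientation, solute–lipid contacts), which makes biased
sampling along *z* both slow to converge and prone to underestimating the
entry barrier ΔG‡.

`memfes` implements the full protocol that addresses this, end to end, on
analytically tractable toy systems:

1. **Exploration** — OPES *expanded* sampling of a multithermal ensemble
   (270–500 K) with shared-bias walkers, so insertion/exit transitions
   occur without committing to a CV;
2. **Featurization** — per-frame minimum distances between each solute
   bead and each group of identical lipid sites (B×G features; 15×12 = 180
   in the default system), plus the z-distance and z-dipole validation
   coordinates;
3. **CV learning** — *Deep-TICA*: a tanh network (d–128–64–4) trained with
   Adam so the leading time-lagged eigenvalues of its outputs are maximal;
   the leading mode, scaled to [−1, 1] with +1 = water and −1 = membrane,
   becomes the sampling CV. The network, the backpropagation through the
   generalized eigenproblem Cτv = λC0v, and the rescaled-time handling of
   biased training data are implemented in the package;
4. **Biased sampling** — *OPES MetaD* along the learned CV: Gaussian
   kernels rebuild the CV's marginal probability on the fly and the bias
   V(s) = (1−1/γ)·k_BT·log(ε + (1−ε)·p̃(s)/p_max) is capped at the 60
   kJ/mol barrier parameter by construction; 8 replicas share one bias;
5. **Analysis** — reweighted free-energy surfaces F(s) = −k_BT·log p(s)
   along any coordinate, basin ΔG from Boltzmann integrals, barriers ΔG‡,
   block-bootstrap errors over walkers;
6. **Experimental comparison** — saturation-binding fits
   F(L) = F0 + A·L/(K_D + L) to fluorescence titrations, K_D → ΔG =
   RT·ln(K_D[M]/1 M) via the mole-fraction-weighted lipid molar mass, and
   a computational-vs-experimental discrepancy table.

Every sampling estimator is validated against deterministic quadrature on
toy potentials with programmed thermodynamics (`analyticFes`), not against
another sampler.

## Worked example

A double well with a programmed −6 kJ/mol insertion free energy and a
12 kJ/mol barrier, sampled with OPES MetaD and compared with the exact
quadrature oracle:

```r
library(memfes)

spec <- doubleWellSpec(barrier = 12, deltaG = -6)
sys  <- buildSystem(spec, seed = 1)

cv  <- function(x) list(value = x[1, 1], grad = matrix(1, 1, 1))
st  <- newOpesState(barrier = 60, temperature = 310,
                    sigma0 = estimateSigma0(sys, cv, seed = 9), stride = 500L)
eng <- opesEngine(st, cv, temperature = 310)
tr  <- runLangevin(sys, nSteps = 2e5, dt = 0.05, temperature = 310,
                   seed = 11, bias = eng, stride = 10L)

g      <- seq(-1.7, 1.7, length.out = 69)
fes    <- fesNd(tr@frames[, 1, 1], frameWeights(tr), g, temperature = 310)
oracle <- analyticFes(spec, "x", g, 310)
basinAnalysis(fes,    c(0.1, 1.7), c(-1.7, -0.1))
#> BasinResult: dG = -5.99 +/- 0.37 kJ/mol, barrier = 10.75 kJ/mol at 0.2
basinAnalysis(oracle, c(0.1, 1.7), c(-1.7, -0.1))
#> BasinResult: dG = -5.97 +/- 0.00 kJ/mol, barrier = 10.05 kJ/mol at 0.15
```

The sampled surface recovers the programmed basin free-energy difference
(−5.99 ± 0.37 vs the exact −5.97 kJ/mol) and the barrier within the
bootstrap error. The experimental-side module works the same way on a
synthetic titration at the published design (0–1.0 mg/mL, n = 5, 2%
noise):

```r
fit <- bindingFreeEnergy(fitBinding(generateBindingData(
  A = 120, KD = 0.013, noiseSd = 2, nReplicates = 5, seed = 3)))
fit
#> BindingFit: K_D = 0.01371 +/- 0.00031 mg/mL, F0 = 101.5%, A = 118.7%, dG = -27.00 +/- 0.06 kJ/mol
compareAffinities(c(toy = -5.99), c(toy = -8.5))
#>   compound dG_computational dG_experimental discrepancy pass
#> 1      toy            -5.99            -8.5        2.51 TRUE
```

The full two-phase pipeline (exploration → featurize → train CV → CV-biased
sampling → FES → binding comparison) runs from one configuration object:

```r
report <- runProtocol(protocolConfig(
  spec = miniBilayerSpec(),
  phase1 = list(steps = 10000, walkers = 4L),
  phase2 = list(steps = 5000, walkers = 4L),
  train = trainConfig(lag = 0.002, maxEpochs = 80),
  binding = list(KD = 0.013), seed = 1L))
```

and reports the Deep-TICA eigenvalues, the CV's basin-separation ROC area
and sign convention, ΔG/ΔG‡ along both the z-distance and the learned CV
with errors, and the affinity comparison. See the methods vignette
(`vignettes/memfes-methods.Rmd`) for the model definitions, parameter
conventions and numerical choices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the end-to-end protocol on the default mini-bilayer at desk scale
(reduced run lengths, seeded from `--seed`), prints the resulting CV
diagnostics, free-energy estimates and binding comparison, and writes the
machine-readable report to `--out`.
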