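Package: memfes
Title: Enhanced Sampling and Machine-Learned Collective Variables for
    Solute-Membrane Insertion Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for computing solute-membrane insertion
    free energies with adaptive-bias enhanced sampling and machine-learned
    collective variables. Provides Langevin-dynamics toy systems with
    analytically known thermodynamics (double wells, a coupled 2D insertion
    model, and a particle-based mini-bilayer with typed lipid sites and a
    charged solute chain), minimum-distance descriptor featurization,
    time-lagged independent component analysis (TICA) and its deep
    neural-network extension (Deep-TICA) for learning slow collective
    variables, on-the-fly probability enhanced sampling (OPES) bias engines
    in both the well-tempered (MetaD) and multithermal expanded-ensemble
    flavors with shared-bias walkers, reweighted free-energy surfaces with
    basin free-energy differences and barriers, and saturation-binding
    analysis of fluorescence titrations (K_D fitting and conversion to
    binding free energies) for comparing computational and experimental
    affinities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
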