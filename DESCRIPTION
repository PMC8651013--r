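Package: hlaflex
Title: Pressure/Temperature Free-Energy Surfaces and Correlated-Motion
    Networks for Peptide-HLA Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two complementary measures of peptide-HLA (pHLA) conformational
    flexibility. The thermodynamic arm fits tryptophan emission spectra
    collected over a pressure/temperature grid with a skewed-Gaussian line
    shape, converts integral intensities into two-state equilibrium constants
    and free energies, and fits the resulting Delta-G matrix to a six-parameter
    Hawley-type pressure/temperature surface. The simulation arm analyses
    molecular-dynamics trajectory ensembles: two-stage superposition to an
    average structure, per-replica C-alpha RMSF profiles and cross-complex
    Delta-RMSF with replica-level significance testing, binding-groove width
    distributions, dynamic cross-correlation matrices, and Girvan-Newman
    community network analysis of the correlation graph. Synthetic-data
    generators with known ground truth (two-state spectral mixtures on the
    experimental grid; multivariate-Gaussian trajectory ensembles with planted
    per-residue variances and inter-residue correlations) make every stage
    testable without access to raw spectra or trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
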