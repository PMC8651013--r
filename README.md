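# hlaflex

Flexibility analysis of peptide–HLA (pHLA) class I complexes, by two
complementary computational routes:

1. **Thermodynamic arm.** Pressure/temperature-resolved tryptophan emission
   spectra are fitted with a skewed-Gaussian line shape, integral intensities
   are converted to two-state equilibrium constants
   (`f = K/(1+K)`, `ΔG = −RT ln K`), and the resulting ΔG(p,T) matrix is
   fitted with the six-parameter Hawley-type surface

   ```
   ΔG(P,T) = ΔG0 + ΔV0 (P−P0) + Δα (P−P0)(T−T0) + (Δβ/2)(P−P0)²
             − ΔS0 (T−T0) − ΔCp [T(ln(T/T0) − 1) + T0]
   ```

   yielding per-complex estimates (± SE) of ΔG0, ΔS0, ΔCp, ΔV0, Δβ and Δα —
   the thermodynamic fingerprint of the conformational equilibrium that the
   bound peptide tunes.

2. **Simulation arm.** Molecular-dynamics trajectory ensembles are superposed
   in two stages (fit to reference → average → refit to average), reduced to
   per-replica C-alpha RMSF profiles, cross-complex ΔRMSF with per-residue
   two-sample significance testing, binding-groove width distributions
   (triplet-centroid distances D1–D4), dynamic cross-correlation matrices
   (DCCM), and community networks: residue graphs filtered at |C| ≥ 0.4 and
   an 8 Å / 100 %-of-frames contact rule, clustered by divisive
   Girvan–Newman with weighted-modularity selection.

Because the underlying raw spectra and trajectories are typically not
available, the package also ships first-class synthetic generators — two-state
spectral mixtures driven by a planted surface on the experimental
5 temperature × 5 pressure grid, and multivariate-Gaussian trajectory
ensembles with planted per-residue variances and inter-residue correlations —
so every stage of both arms is testable against known ground truth.

The package is written for structural immunologists and biophysicists who
analyse pHLA (or comparable receptor–ligand) flexibility, in the base-R /
bio3d idiom; graphs are igraph objects throughout.

## Worked example

Plant a surface, synthesise a noiseless spectra matrix on the experimental
grid, and run the full thermodynamic pipeline:

```r
library(hlaflex)

truth <- thermo_surface_params(deltaG0 = 8.1, deltaS0 = -0.07, deltaCp = -0.6,
                               deltaV0 = 2, deltaBeta = -1.3, deltaAlpha = 3.4)
model <- two_state_spectral_model(
  state_a = list(f_max = 100, lambda_max = 340, w = 60, b = 0.1),
  state_b = list(f_max = 60,  lambda_max = 365, w = 70, b = -0.05),
  thermo = truth, noise_sd = 0)
spectra <- generate_spectra_matrix(model, default_pt_grid(n_replicates = 1L),
                                   seed = 42)

wl <- sort(unique(spectra$wavelength_nm))
Fa <- integrate_intensity(emission_spectrum(
  wl, evaluate_skewed_gaussian(wl, 100, 340, 60, 0.1)))
Fb <- integrate_intensity(emission_spectrum(
  wl, evaluate_skewed_gaussian(wl, 60, 365, 70, -0.05)))

res <- run_pt_pipeline(spectra, config = list(normalisation = "reference"),
                       F_a = Fa, F_b = Fb)
res$surface
#> Delta-G(P,T) surface fit (25 conditions, unweighted)
#>   deltaG0    =        8.1 +/- 4.1e-12
#>   deltaS0    =      -0.07 +/- 6.5e-13
#>   deltaCp    =       -0.6 +/- 1.7e-11
#>   deltaV0    =          2 +/- 8.4e-11
#>   deltaBeta  =       -1.3 +/- 9.7e-13
#>   deltaAlpha =        3.4 +/- 3.1e-12
#>   R^2        = 1.000000
```

All six planted parameters are recovered: ΔG0 = 8.1 kJ·mol⁻¹ at the reference
point (5 MPa, 283.15 K), the entropic term ΔS0 = −0.07 kJ·mol⁻¹·K⁻¹, and so
on, with standard errors at machine precision because the input is noiseless.

The simulation arm, on a planted two-block ensemble (residues 1–10 and 11–20
internally correlated at ρ = 0.8, uncorrelated across blocks):

```r
topo <- generate_toy_structure(20, "extended")
R <- matrix(0, 20, 20); R[1:10, 1:10] <- 0.8; R[11:20, 11:20] <- 0.8; diag(R) <- 1
tr <- generate_trajectory(planted_dynamics_model(topo, 0.5, R, n_frames = 4000),
                          seed = 1)
C <- compute_dccm(tr)
round(c(C["A:1", "A:2"], C["A:1", "A:11"]), 3)
#> [1]  0.800 -0.001

best <- select_community_number(girvan_newman(build_network(C, threshold = 0.4)))
best
#> community_partition: k = 2, Q = 0.5000
community_graph(best, C)
#> community_network: 2 communities (sizes 10, 10), 0 inter-community edge(s)
```

The DCCM reads back the planted intra-block correlation (0.8) and the absence
of inter-block coupling; Girvan–Newman clustering recovers exactly the two
planted blocks at the maximal modularity Q = 0.5.

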