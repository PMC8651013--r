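---
title: "Models and methods behind hlaflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hlaflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaflex)
```

hlaflex quantifies conformational flexibility of peptide–HLA (pHLA) class I
complexes by two complementary routes: a thermodynamic route, which converts
pressure/temperature-resolved tryptophan fluorescence into a two-state
free-energy surface, and a simulation route, which reduces molecular-dynamics
trajectory ensembles to per-residue fluctuation profiles, binding-groove
geometry, and community networks of correlated motion. This vignette explains
the models, the tunable parameters, the synthetic-data generators that make the
pipeline testable, and the numerical decisions taken where the design was
genuinely open.

## The thermodynamic arm

### Spectral model

A tryptophan emission scan is described by a four-parameter skewed Gaussian:
peak intensity $f_{max}$, peak wavelength $\lambda_{max}$ (nm), full width at
half maximum $w$ (nm), and dimensionless skewness $b$:

$$f(\lambda) = f_{max}\exp\!\left(-\ln 2\left[\frac{\ln\!\big(1 +
  2b(\lambda-\lambda_{max})/w\big)}{b}\right]^2\right).$$

Two numerical choices matter. First, the expression is 0/0 at $b = 0$; for
$|b| < 10^{-8}$ the code switches to the analytic limit, the plain Gaussian
$f_{max}\exp(-4\ln 2\,(\lambda-\lambda_{max})^2/w^2)$. Second, where the
logarithm's argument is non-positive the model evaluates to 0 rather than
erroring: that is the line shape's genuine zero tail, and returning 0 keeps
least-squares objectives defined when an optimiser wanders near the support
edge. Fits are Levenberg–Marquardt with data-driven starting values
($f_{max}$ and $\lambda_{max}$ from the maximum point, $w$ from the empirical
FWHM, $b = 0$) and are unweighted by default; per-point weights can be passed
when replicate scans provide standard deviations. Buffer blanks are assumed
subtracted upstream; `subtract_blank()` covers data where they were not.

### From intensities to an equilibrium grid

The quantity carried forward is the integral emission intensity $F_i$
(trapezoidal, by default over the full measured 325–500 nm window — the
integration window is configurable because no canonical sub-window exists).
Under a two-state model, the population fraction $f$ of one conformational
substate satisfies $f = K/(1+K)$ and $\Delta G = -RT\ln K$ with
$R = 8.314\times10^{-3}$ kJ·mol⁻¹·K⁻¹.

Mapping raw integrals onto $f$ requires a normalisation, and the right choice
depends on what is known:

* **minmax** (default): $f = (F - F_{min})/(F_{max} - F_{min})$ over the full
  p/T matrix of one complex. With no access to pure-substate spectra this maps
  the observed signal range onto the population fraction; it is exact only
  when the experiment actually drives the system from one substate to the
  other across the grid.
* **reference**: $f = (F - F_B)/(F_A - F_B)$ given the pure-state integrals.
  This is exact whenever the endpoint spectra are known — in particular for
  synthetic data, where the generator knows both states; all planted-recovery
  tests use it, because a planted surface whose fractions span only part of
  (0, 1) is not identifiable under minmax rescaling.
* **tempsum**: division by the per-temperature intensity sum, for designs
  where the total signal drifts with temperature.

Fractions are clipped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-4}$ so $\ln K$ stays finite at saturated grid points;
clipped conditions are reported. Replicate scatter is propagated to
$\mathrm{sd}(\Delta G) = RT\,\mathrm{sd}(f)/(f(1-f))$, the first-order
expansion of $-RT(\ln f - \ln(1-f))$.

### The free-energy surface

The $\Delta G(P,T)$ matrix is fitted with the six-parameter Hawley-type
quadratic expansion around a reference point $(P_0, T_0)$:

$$\Delta G = \Delta G_0 + \Delta V_0\,\Delta P + \Delta\alpha\,\Delta P\,\Delta T
  + \tfrac{\Delta\beta}{2}\Delta P^2 - \Delta S_0\,\Delta T
  - \Delta C_p\!\left[T\big(\ln\tfrac{T}{T_0}-1\big)+T_0\right]$$

with $\Delta P = P - P_0$, $\Delta T = T - T_0$. Internal units are MPa, K and
kJ·mol⁻¹; $\Delta V_0$ (cm³·mol⁻¹), $\Delta\beta$ (cm³·mol⁻¹·MPa⁻¹) and
$\Delta\alpha$ (cm³·mol⁻¹·K⁻¹) enter through 1 cm³·MPa·mol⁻¹ = 1 J·mol⁻¹.
The heat-capacity bracket is the standard Hawley form; it vanishes at
$T = T_0$, so the surface reduces to $\Delta G_0$ exactly at the reference
point for any parameter set — a property the test suite asserts. Both
$\Delta C_p$ and $\Delta\alpha$ are treated as pressure- and
temperature-independent, and the two-state assumption is kept throughout: more
states would not be identifiable from a 5 × 5 grid without overfitting.

The default reference point is the lowest experimental condition,
$P_0 = 5$ MPa (50 bar) and $T_0 = 283.15$ K (10 °C); both are arguments.

Although the fit is usually described as nonlinear least squares, the surface
is exactly linear in its six parameters, so the weighted least-squares
solution via the derived regressors is the global optimum of the same
objective, and the reported standard errors — from the weighted
normal-equations covariance — are those of the "linearised" problem, which
here is not an approximation. Weights are $1/\mathrm{sd}^2$ when replicate
standard deviations are available. A rank-deficient design (for example a
single pressure level, which makes every pressure regressor collinear) is
refused with the near-dependent parameter pair named.

## The simulation arm

### Superposition

Fluctuations are only meaningful in a common frame. The two-stage protocol
fits every frame to the reference structure by rigid-body least squares
(Kabsch, via bio3d) on a C-alpha selection, averages the fitted coordinates,
and refits every frame to that average; replicas are combined before
averaging so the whole ensemble shares one frame. The selection should be
restricted to conformationally stable residues (helix cores, sheet strands):
the fit absorbs whatever collective motion the selection contains, so fitting
on mobile regions systematically deflates their apparent fluctuations and can
induce spurious anticorrelation between independently moving parts. This is
visible in synthetic ensembles — superposing a small system on all of its
atoms noticeably distorts planted correlations, while driving the fit from a
quiet scaffold preserves them — and is why the pipeline takes an explicit
`fit_selection`.

### RMSF, ΔRMSF and significance

Per replica and per residue, $\mathrm{RMSF} = \sqrt{\langle|\mathbf r -
\langle\mathbf r\rangle|^2\rangle}$ over the frames retained after discarding
an initial equilibration period (default 10 ns, converted to frames through
the snapshot interval; the conventional production design is 10 replicas of
150 ns at 10 ps snapshots, 9 µs total across six complexes). For isotropic
Gaussian displacements of per-axis standard deviation $\sigma$ the closed
form is $\sigma\sqrt3$, which the generators reproduce within sampling error.

ΔRMSF compares complexes: per residue, each complex's replica-mean RMSF minus
the grand mean over complexes, so rows sum to zero. The sign convention is a
flag: the default `"flexibility"` means positive = more flexible than
average; `"rigidity"` flips it. Both conventions appear in the literature and
neither is asserted as canonical.

Significance is assessed per residue by a two-sample test between the most
and the least flexible complex (by replica-mean RMSF), with replicas as the
statistical unit. The test is Welch's by default (the variant is
configurable), two-sided, with no multiple-testing correction unless
Benjamini–Hochberg is requested. Two properties of this procedure matter for
interpretation and are verified by simulation in the test suite:

* with exactly two complexes the max/min selection is the identity, and the
  null rejection rate equals the nominal $\alpha$ (5 %);
* with more complexes the selection step reuses the data that the test then
  sees, inflating the null rate. For 6 complexes × 10 replicas at
  $\alpha = 0.05$ the measured null rejection rate is **0.327** (20 000
  simulated null residues). Per-residue significance calls from this
  procedure are therefore comparative flags, not calibrated error rates.

### Groove widths

Each of the four groove measurements D1–D4 is the distance between the
centroids of two triplets of C-alpha atoms, one per groove helix, evaluated
per frame. Centroids are unweighted (identical atoms). The published triplet
positions are shown only graphically, so the defaults here are illustrative
positions spanning the N-terminal, central and C-terminal groove — users
analysing real structures must supply their own triplets. Distances are
invariant under rigid motion of a whole frame, so superposition does not bias
them.

### DCCM

The dynamic cross-correlation between residues $i$ and $j$ is

$$C_{ij} = \frac{\langle \Delta\mathbf r_i\cdot\Delta\mathbf r_j\rangle}
  {\sqrt{\langle|\Delta\mathbf r_i|^2\rangle\,\langle|\Delta\mathbf r_j|^2\rangle}}$$

over C-alpha displacement vectors from the mean structure of the combined,
refitted ensemble (per-replica matrices are available but the combined matrix
is the default, matching how replica simulations are usually pooled). A
residue with zero variance has no defined correlation and is reported by
name. For peptide-focused inspection the square matrix can be truncated to
selected rows against all remaining residues.

### Community network analysis

The correlation graph has an edge between residues when three conditions
hold: the pair is distinct, $|C_{ij}|$ reaches the edge threshold (default
0.4 — anticorrelation counts by magnitude, since the filter is written
$|0.4|$), and the pair is in persistent contact — C-alpha distance within
8 Å in at least the required fraction of frames, default 100 % ("throughout
the simulation"). Edges carry $|C|$ and the betweenness length $-\log|C|$,
so stronger correlation means a shorter communication path; this follows the
convention of the community-network protocol this analysis descends from.
The length is floored at $10^{-12}$ to keep weights positive at $|C| = 1$.

Community detection is divisive Girvan–Newman: repeatedly delete the edge of
highest weighted betweenness, and each time the component count grows record
the partition together with Newman's weighted modularity $Q$ evaluated on the
*original* graph with $|C|$ weights. Isolated residues stay as singleton
communities. The reported partition is the $Q$-maximum by default (ties break
to fewer communities), but a preferred community count is accepted whenever
its $Q$ is within 0.02 of the maximum — the tolerance used when partitioning
several similar complexes alike, and it is configurable. On small graphs the
recorded $Q$ values are checked against direct summation of the modularity
formula and the best recorded partition against exhaustive search over all
set partitions.

The community-level network reports one node per community (size = residue
count) and, between communities, the summed $|C_{ij}|$ over masked,
above-threshold residue pairs spanning them; zero-strength edges are omitted.

## Synthetic generators: what they emulate, and what they do not

The study's raw fluorescence matrices and trajectories are not deposited, so
the package ships generators whose ground truth is known exactly.

* **Spectra**: two fixed skewed-Gaussian substates mixed at every grid
  condition by $f = K/(1+K)$, $K = e^{-\Delta G(p,T)/RT}$, with additive
  i.i.d. Gaussian noise per wavelength (no noise model is published; i.i.d.
  Gaussian is the neutral choice). The default grid is the experimental
  design: 10–30 °C in 5 °C steps × 50/400/800/1200/1600 bar, in triplicate.
* **Trajectories**: frames are the reference plus zero-mean Gaussian
  displacements with planted per-residue standard deviations and a planted
  residue × residue correlation matrix applied identically to x, y and z.
  The identical-per-axis choice is deliberate: it makes the vector-dot DCCM
  equal the planted scalar $\rho$ exactly
  ($3\rho\sigma_i\sigma_j / 3\sigma_i\sigma_j = \rho$), giving an analytic
  oracle. Correlation matrices are validated symmetric with unit diagonal;
  eigenvalues down to $-10^{-8}$ are clipped to zero with the repair logged,
  anything worse is refused with the offending eigenvalue named.

Both generators are pure functions of their inputs and a seed. What they do
**not** emulate: force-field physics, solvent, anharmonicity, slow
conformational exchange, or autocorrelation in time (frames are independent
draws). Passing tests therefore demonstrate that the *estimators* are
correct — that RMSF, DCCM, the surface fit and the community pipeline recover
what was planted — not that real pHLA trajectories behave like Gaussian
ensembles. Statistical conclusions about real systems still depend on
simulation quality and sampling.

## Problem sizes and test budgets

The suite's stochastic checks use sizes chosen so that sampling error is well
inside the asserted tolerances while the whole suite stays quick: 50 000
frames for correlation recovery (±0.02), 10 000 frames for the RMSF closed
form (2 %), 100 repetitions for surface bias/coverage, 1 000 simulated null
residues for test calibration (binomial error ≈ 1.5 percentage points), and
4 000 frames for two-block community recovery. Exhaustive modularity search
is run on 10-node graphs (115 975 partitions).

## Known limitations

* The minmax normalisation presumes the p/T grid spans the two-state
  transition; outside that regime $\Delta G$ estimates are rescaled by an
  unknown affine transformation of $f$.
* The per-residue significance procedure's null rate is calibrated only for
  the replica/complex counts documented above; other designs should re-run
  the calibration simulation.
* Girvan–Newman on the recorded hierarchy does not guarantee the global
  modularity optimum on arbitrary graphs; agreement with exhaustive search is
  asserted on the clique-bridge topologies the tests use.
* XTC trajectories are not read; use DCD or multi-model PDB.
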