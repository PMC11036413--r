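---
title: "Strain-dependent transverse conduction velocity in ventricular monodomain simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-dependent transverse conduction velocity in ventricular monodomain simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(strainwave)
```

## The model

Chronic infarcts change how electrical wavefronts travel through the
ventricular wall. Conventional infarct models slow conduction only inside
the image-detectable *structural* border zone (BZ). `strainwave` implements
an extension in which the conduction velocity transverse to the myofibers,
$CV_T$, also responds to the local mechanical load, so that mechanically
impaired but structurally normal tissue adjacent to a scar — a *functional*
border zone — conducts slowly as well:

$$CV_T(x) \;=\; CV_{T,\mathrm{ref}} \; f_{\mathrm{act}}(x)\;
  g\!\left(\varepsilon_a(x)\right), \qquad
g(\varepsilon_a) \;=\; 1 + \frac{CV_{T,\mathrm{var}}}{2\,CV_{T,\mathrm{ref}}}
  \tanh\!\big(\alpha\,(\varepsilon_a - \varepsilon_{\mathrm{ref}})\big).$$

Here $\varepsilon_a$ is the fiber-strain amplitude (peak-to-peak logarithmic
fiber strain over a cardiac cycle), $f_{\mathrm{act}} \in [0,1]$ the
infarct-density factor (1 healthy, 0 in the core, linear across the BZ),
and the sigmoid $g$ maps strain amplitude to a velocity factor. Default
parameters: $CV_{T,\mathrm{ref}} = 0.30$ m/s, $CV_{T,\mathrm{var}} = 0.44$
m/s, $\alpha = 20.6$, $\varepsilon_{\mathrm{ref}} = 0.1665$. These bound
$CV_T$ to $[0.08, 0.52]$ m/s in non-fibrotic tissue; at
$\varepsilon_a = \varepsilon_{\mathrm{ref}}$ the law returns exactly
0.30 m/s, and the lower bound matches the constant 0.08 m/s that the
*reference* (strain-independent) model assigns to the whole structural BZ.

Membrane voltage is solved with the monodomain equation
$\beta C_m \partial_t V_m + I_{\mathrm{ion}} - \nabla\!\cdot\!\sigma_m
\nabla V_m = \beta I_{\mathrm{ext}}$ with $\beta = 0.14\,\mu m^{-1}$,
$C_m = 1\,\mu F/cm^2$, zero-flux boundaries, and a transversely isotropic
conductivity tensor
$\sigma_m = \sigma_L \vec e_f \vec e_f^{\,T} + \sigma_T (I - \vec e_f \vec
e_f^{\,T})$ assembled per element from the fiber direction. Membrane
kinetics are the Ten Tusscher–Panfilov (2006) human ventricular model
(epicardial base formulation), implemented in C++ with Rush–Larsen gating
updates driven by voltage lookup tables.

### Cell phenotypes

All four transmural layers derive from one base cell purely through the
slow delayed-rectifier conductance: Gks is scaled by 2.10 (endo), 0.95
(sub-endo), 1.30 (mid) and 2.45 (epi). Structural-BZ remodeling
additionally multiplies GNa by 0.38, GCaL by 0.31, GKr by 0.30 and GKs by
0.20 (composition with the layer factor is multiplicative; a
`bz_layer_gradient = FALSE` switch collapses the BZ to a single phenotype).
Cells are conditioned with 500 beats at a basic cycle length of 600 ms
(2 ms, 40 µA/cm² stimuli) before tissue runs; the conditioned states are
cached per phenotype.

At steady state the four phenotypes have intrinsic action potential
durations of about 240, 291, 271 and 231 ms. The package measures
*intrinsic* (isolated-cell) APD from the maximum-upstroke time to a
**−75 mV** repolarization crossing — the convention under which the four
layer phenotypes reproduce the published 242/294/274/232 ms transmural set
to within 3.5 ms. Tissue-level repolarization (repolarization maps,
manifested APDs) uses the **−70 mV** downward crossing throughout. The two
thresholds differ because the isolated-cell convention of the source data
is not uniquely determined by the tissue definition; the sensitivity is
about 0.7 ms per mV of threshold in the final repolarization tail, and the
choice is exposed as the `repol_threshold` argument everywhere.

## Numerics

* Geometry: meshes are simplicial — segments (cables), triangles (sheets),
  tetrahedra (slabs, ventricle). The idealized left ventricle is a
  basally-truncated prolate ellipsoid shell solved so that cavity and wall
  volumes match their targets (44 and 136 mL by default); the wall is a
  uniform offset between two confocal-aspect ellipsoids, meshed
  structurally in (transmural, apex–base, circumferential) coordinates and
  subdivided into tetrahedra with a Freudenthal (Kuhn) template, which is
  conforming on structured grids. At 1 mm resolution the integrated wall
  volume is within 0.1% of the target.
* Sheets use a hexagonal (equilateral-triangle) lattice. Triangulated
  square lattices bias the diagonal conduction velocity by 6–9% at
  0.25–0.5 mm; the 6-fold symmetric lattice keeps isochrones circular to
  about 1%.
* Fibers follow a rule-based transmural helix, linear in the transmural
  coordinate from +60° (endo) to −60° (epi), lying in the local
  circumferential–longitudinal plane. Fixtures take uniform fibers along
  the first axis.
* Time stepping: operator splitting at dt = 20 µs — explicit lumped-mass
  finite-element diffusion plus Rush–Larsen/forward-Euler membrane
  kinetics. At the resolutions used (0.25–1 mm) the explicit diffusion
  stability bound is an order of magnitude above dt; halving dt changes a
  cable CV by about 1%. Single cells use the same kernel, so intrinsic and
  tissue kinetics are bit-compatible.
* Conductivity calibration: the eigenvalue needed for a CV target is found
  by bisection on planar-wave cable simulations *at the same mesh spacing*
  (numerical CV depends on h), to 0.5% relative tolerance, cached per
  (target, resolution, phenotype). Diffusion blow-up and excitation
  failure (the stimulus charge diffusing away at absurdly high
  conductivity) are both treated as "too fast" during bracketing. Targets
  below the propagation limit of a given spacing — discretized strain-law
  levels can reach a few cm/s — are extrapolated from the slowest
  calibrable level through the CV ∝ √σ monodomain scaling and flagged; in
  tissue such elements conduct marginally or block, which is the intended
  physiology of near-zero $CV_T$.
* $CV_T$ discretization: the continuous law is binned into 9 equal-width
  levels over the positive range and each node takes its bin center; the
  exact-zero core is preserved as its own level, so "9 levels" and "10
  including zero" are both accurate descriptions. Element tensor values
  snap to the field's own level set.
* Activation is recorded as the time of maximum upstroke velocity within
  an upstroke episode (committed once the upstroke passes −20 mV);
  sub-threshold bumps that never reach −20 mV are not activations.

## The synthetic strain generator

The mechanics side of weak coupling is emulated, not computed: a
finite-element mechanics model is out of scope here. The generator
reproduces the spatial structure that matters for the electrophysiology:

* remote tissue: $\varepsilon_a$ decreases linearly from the endocardium
  (default 0.21) to the epicardium (default 0.12), bracketing the
  reference strain 0.1665 mid-wall, so the healthy transmural $CV_T$
  spans roughly 0.14–0.48 m/s with higher values toward the endocardium;
* structural BZ: amplitudes depressed to a plateau (default 0.15), because
  the stiff core suppresses filling strain while contractile function is
  mostly retained;
* infarct core: elevated amplitudes (default 0.25) from passive systolic
  bulging;
* smooth blending over a transition width (default 5 mm) that extends the
  depressed amplitudes *beyond* the structural BZ — this halo is what the
  strain-CV law converts into the functional border zone;
* optional Gaussian node noise smoothed by one neighbor-averaging pass,
  reproducible by seed.

What passing tests on these fields do **not** show: the generator has no
force balance, no pressure–volume loop, no dyssynchronous activation
feedback, and its transmural profile endpoints are configuration values
rather than measurements. Conclusions about real mechanics require a real
mechanics model; the generator only guarantees the *orderings* the
electrophysiology consumes (endo > epi remote strain; depressed BZ;
bulging core; halo).

## Virtual stress test

The S1–S2 protocol delivers a drive train (default six S1 at 600 ms) and a
premature S2 (3 mm stimulus footprint, 40 µA/cm², 2 ms), scanning coupling
intervals at 5 ms steps from the earliest capturing interval to 15 ms past
the latest VT-inducing one. VT is defined as electrical activity sustained
for at least 800 ms after S2, operationalized as new upstrokes occurring in
every 100 ms sub-window; the exit point is the node with the earliest
second post-S2 activation (ties to the lowest node index). The scan chains
state checkpoints across S2 intervals so the drive train is simulated once
per site.

The package's desk-scale reentry substrate is an annulus fixture: a 34 mm
sheet with a central transmural scar disc (7.5 mm radius, 4 mm BZ), planar
S1 from one edge and S2 beside the obstacle inside the S1 repolarization
gradient. In the reference variant the circulating pathway is barely
longer than the refractory wavelength and VT is inducible at a single
scanned interval; the strain-derived $CV_T$ halo of the extended variant
slows the circuit and widens the vulnerable window to twice that. The
same paired design shows the substrate metrics: the extended variant
roughly doubles the tissue volume carrying repolarization-time gradients
≥ 10 ms/mm (RTG$_{vol}$) while moving the mean gradient within that volume
(RTG$_{mean}$) by only a few percent.

These fixtures are deliberately small (thousands of nodes, one pacing
site, 10–15 ms scan steps); they demonstrate mechanisms and orderings, not
the absolute window widths or RTG volumes of a full-resolution ventricle
(~10⁶ degrees of freedom), which are outside desk scale.

## Worked example

```{r example}
library(strainwave)

# law anchors
p <- strain_cv_params()
cvt_field(0.1665, 1, p)         # 0.30 m/s at the reference strain
p$cvt_ref - p$cvt_var / 2       # 0.08 m/s asymptotic minimum

# intrinsic APD of the endocardial phenotype (500 beats at BCL 600)
intrinsic_apd("endo")           # ~240 ms

# a coupled transmural cable: manifested APD range
lv  <- build_lv_mesh(136, 44, resolution = 2.5)
cab <- assign_layers(build_fixture("cable",
                                   attr(lv, "geometry")$wall_offset, 0.25))
sig <- calibrate_conductivity(0.3, "transverse", resolution = 0.25)
s6  <- assemble_conductivity(cab, 0.3,
         structure(rep(0.3, nrow(cab$nodes)), levels = 0.3),
         structure(as.numeric(sig), names = sprintf("%.6f", 0.3)))
rec <- solve_monodomain(cab, s6, duration = 4000,
         stimuli = lapply(0:5 * 600, function(on)
           stimulus_spec(c(0, 0, 0), diameter = 2.1, onset = on)))
apd <- rec$rep[, 6] - rec$act[, 6]
diff(range(apd, na.rm = TRUE))  # ~46 ms transmural APD range
```

## Design decisions and open choices

* **Base cell variant.** The transmural APD set is reproduced from the
  *epicardial* 2006 formulation for all layers; the endocardial variant
  (smaller Ito, slower s-gate) shifts all APDs several ms shorter and was
  rejected against the published values.
* **Fitting objective.** `fit_strain_cv()` fits the sigmoid either to an
  OLS regression line through the samples (mirroring a combined-dataset
  regression) or to the raw points; parameter recovery is validated on
  synthetic samples because the source datasets exist only as figures.
* **Layer thicknesses** default to equal quarters; the intrinsic APD
  targets are single-cell quantities and the manifested range uses the
  layer sequence, not the exact fractions.
* **Infarct angular extent** is not a printed quantity; the default
  (0.15 rad) was chosen once so the transmural case's total infarct
  (core + BZ) volume integrates to ≈ 15 mL on the default geometry.
* **BZ distance** is Euclidean distance to the nearest core node — adequate
  at 9 mm scale on a smooth shell and cheap.
* **Fixture phenotype.** Protocol fixtures label all cells epicardial
  (shortest APD): desk-scale reentrant circuits need recovery times
  compatible with centimeter path lengths.
* **Known limitations.** No bidomain effects, no beat-resolved
  mechano-electric feedback (the coupling is a static, remodeling-time-
  scale map from strain amplitude to $CV_T$), no deformation of the
  diffusion tensor, single-precision-scale agreement between cable and
  sheet calibration (~1.5%), and VT inducibility on desk-scale fixtures is
  an all-or-nothing outcome sensitive to geometry — as it is at full
  scale.
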