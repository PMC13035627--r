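---
title: "Autoprogressive elastic-modulus imaging: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoprogressive elastic-modulus imaging: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quasi-static ultrasound elastography presses a linear-array probe a few
millimetres into soft tissue while recording the applied surface force
$f$, the probe displacement $u$, and axial internal displacements
$\hat u_y$ tracked in the scan plane. The inverse problem is to recover
the spatial distribution of the Young's modulus $E(\mathbf{x})$
throughout the three-dimensional volume from these planar measurements.
This package implements the autoprogressive (AutoP) approach: instead of
assuming a parametric constitutive law, two finite-element analyses
propagate the measurements into physically constrained stress and strain
estimates that train a neural constitutive model, which is then probed
to render quantitative modulus images in arbitrary planes.

## The dual-FEA architecture

For each compression plane and load step two linear solves are run on
the same hexahedral mesh of the undeformed volume:

* **Force-driven solve** (`run_fea_sigma()`): the measured total force is
  applied through the rigid probe footprint — the axial degrees of
  freedom of all footprint nodes are tied to a single master carrying the
  total force, modelling a flat rigid compressor — and the bottom surface
  is fully fixed (no-slip support). Its stress field $\sigma(\mathbf{x})$
  at every integration point becomes the training target.
* **Displacement-driven solve** (`run_fea_epsilon()`): the measured axial
  displacements are prescribed at all in-plane measurement nodes, the
  probe displacement at the footprint, the bottom fixed; the remaining
  degrees of freedom are solved with the current material model. Its
  strain field $\varepsilon(\mathbf{x})$ supplies the training inputs.

When the model equals the true material and the measurements are exact,
the two solves coincide — the force-driven solution reproduces the
displacement-driven one to solver tolerance, which is why the rigid-tie
force application was chosen over distributing the force as fixed nodal
loads (a fixed distribution is inconsistent with a rigid flat probe, and
the two solves would then differ even at the true material).

## The neural constitutive model

The Cartesian neural network constitutive model (CaNNCM) factorizes the
spatially varying response into:

* an **MPN** (material property network), a shallow feed-forward map from
  Voigt strain to Voigt stress representing the spatially *averaged*
  behaviour — two tanh hidden layers of 12 units plus a trainable 6×6
  linear term, with the output anchored as
  $\sigma(\varepsilon) = N(\varepsilon) - N(0)$ so zero strain maps to
  exactly zero stress;
* an **SN** (spatial network), a 3-input shallow network (two tanh layers
  of 16 units, softplus-normalized scalar output) returning a strictly
  positive strain scale factor $S(\mathbf{x})$, exactly 1 everywhere at
  initialization.

Stress evaluation is $\sigma = \mathrm{MPN}(S(\mathbf{x})\,\varepsilon)$.
For an isotropic linear response with shared Poisson's ratio,
$S(\mathbf{x}) = E(\mathbf{x})/E_0$ reproduces the heterogeneous
material exactly, so the factorization is complete for the materials in
scope. Young's modulus is probed by a virtual uniaxial-stress test: the
6×6 tangent at a reference strain is inverted to a compliance $C$ and
$E = 1/C_{22}$ (axial). How modulus values are extracted from a
converged model is a package design decision — the compliance probe was
chosen because it is exact for linear responses and agrees with a
brute-force uniaxial fitting oracle to $10^{-6}$ (tested).

Both solver assembly and probing use a single shared base tangent,
evaluated as a symmetric secant over the reference strain scale
($[\sigma(+h e_k) - \sigma(-h e_k)]/2h$ with $h$ the strain
normalization). For linear responses this equals the analytic Jacobian;
for a trained network it samples the strain range the data actually
constrained and ignores curvature wiggle near the origin that the data
do not. The analytic Jacobian (with the $S(\mathbf{x})$ chain factor,
symmetrization and an eigenvalue floor for SPD-ness) remains available
as `material_jacobian()` and is verified against central finite
differences.

## Training and its stabilization

Training follows a staged three-phase schedule
(`new_schedule()`): one pass of MPN training on the first plane with all
scale factors held at 1; then, with the MPN frozen, two SN passes per
plane introduced individually while a history window mixes in the
retained training fields of recently introduced planes; finally four
passes with all planes jointly. One cycle handles one load step (two FEA
executions per active plane); a pass cycles all load steps.

The dual-FEA iteration is a fixed-point map. Away from a measured plane
the strain data are partly determined by the current model (only one
node layer per element slab is pinned by a given plane's measurements at
the 4-mm desk-scale mesh), so single-plane cycles have a loop gain close
to one: small stiffness overestimates reduce the local strain estimate,
which raises the implied scale factor further. Several numerical
measures keep the iteration stable; all are package choices, documented
here because the training procedure itself does not prescribe them:

* **Under-relaxation** (`sn_relax`): each SN cycle trains toward
  $(1-a)\,\sigma_{\text{model}} + a\,\sigma_{\text{data}}$, with
  $a = 0.1$ during individual-plane introduction and $a = 0.7$ in the
  contractive joint phase.
* **Optimizer discipline**: full-batch Adam with a 10-step warmup; the
  MPN's optimizer state persists across cycles while the SN restarts per
  cycle; a divergence guard aborts only on genuinely bad fits.
* **Identifiability anchors**: the FEA strain data lie close to a
  compression-dominated manifold, leaving parts of the averaged
  stiffness unidentified. The MPN's linear term is ridge-anchored to its
  isotropic initialization (with a symmetry penalty), and the tanh
  correction path uses weight decay and a reduced learning rate so it
  only grows where the data demand it.
* **Lax-then-stringent criteria**: the MPN phase stops at 20% relative
  RMS stress error (fitting it tighter provably biases the averaged
  stiffness low, a regression-attenuation effect caused by
  strain-signature variance the initial stress data lack); SN phases
  target 2%.

Training focus follows the focusing strategy: points within 3 mm of a
compression plane always participate; outside, a seeded random 10% are
selected per cycle whenever a multi-plane model is being developed, and
all updates are weighted by
$w(d) = 0.1 + 0.9\,e^{-d^2/2s^2}$, $s = 3$ mm. The history window
retains the full training fields of the two most recently introduced
planes at full weight — stronger anchoring than a fractional window,
adopted after fractional retention showed larger drift during plane
introduction.

## Convergence diagnostics

Three per-pass statistics summarize the training data
(`stress_entropy()`, `strain_reversibility()`, `stress_convergence()`):

* $H(\sigma)$ — Shannon entropy in bits of the stress data, equal-weight
  mean over the six Voigt components, 64 equal-width bins per component
  with edges frozen at the first evaluated pass so later passes share
  support (the estimator construction is a package choice);
* $\eta_\varepsilon$ — normalized mutual information between the strains
  the force-driven solve produced and the displacement-driven strains,
  $I(\varepsilon_\sigma;\varepsilon_\varepsilon)/H(\varepsilon_\varepsilon)$
  per component on shared bins, clamped to $[0,1]$; identical fields give
  exactly 1;
* $\Delta\bar\sigma$ — mean absolute change of the stress data between
  consecutive passes (kPa), over common integration points.

The advisory rule (`advise()`): once $\Delta\bar\sigma$ has stayed below
1% of the volume-mean $|\sigma|$ for two consecutive passes, a
reversibility at or below 0.7 recommends acquiring more measurement
data, higher reversibility recommends stopping; otherwise continue. When
a pass introduces a new plane, statistics are computed on the union of
the new fields and the retained window data, so they read as what the
new plane *adds*.

Note that the histogram mutual-information estimator carries a positive
bias of roughly $(B-1)^2/(2N\ln 2)$ bits for $B$ bins and $N$ points;
with the defaults this is about 0.05 in $\eta$ units at $N = 10^4$, so
reversibility values should be read with that resolution.

## The synthetic-data generator

`phantom_spec()` / `simulate_plane()` emulate gelatin calibration
phantoms: a cube of homogeneous background (7.9 kPa by default) with
embedded stiff spheres or ellipsoids (19.8 kPa, 7.5 mm radius in the
two-sphere configuration), a shared Poisson's ratio of 0.45, compressed
from above by a rigid 11 × 46 mm probe footprint (clipped to the surface
when it overhangs) in 0.5-mm load steps on a rigid no-slip support. The
forward solve uses the true stiffness field; recorded measurements are
the cumulative probe displacement, the total reaction force, and the
exact axial nodal displacements in the scan slab (plane ± half an
element, full depth). Displacement errors are modelled as a smooth bias
field plus optional seeded white noise added to the axial displacements
only, reflecting how speckle-tracking errors behave (bias rather than
variance). A `full_field` mode records all three displacement components
at every node — the ideal-information configuration with no experimental
analog.

What the generator does *not* emulate: RF speckle and echo
decorrelation, elevational beam-width averaging, probe-surface friction,
tissue viscoelasticity or nonlinearity, irregular organ geometry.
Passing tests on these fixtures therefore demonstrates the correctness
of the inversion machinery under its own modelling assumptions, not
robustness to every error source of a physical acquisition.

Poisson's ratio defaults to 0.45 rather than the nearly incompressible
0.499 because full-integration 8-node hexahedra lock as
$\nu \to 0.5$; 0.45 keeps the standard element accurate and is a
configuration knob.

## Problem sizes and accuracy at desk scale

The bundled study configurations (`standard_fixtures()`) are
`two_sphere_full` (50-mm cube, 2-mm mesh, seven parallel planes 4 mm
apart — 15 625 elements), a reduced `two_sphere_desk` (32-mm cube, 4-mm
mesh, three planes through the sphere centres — 512 elements), and
`homogeneous_desk`. The tests and the bundled analyses run at the
reduced scale, where a full schedule completes in a few minutes on one
CPU core.

Accuracy at the reduced scale is materially worse than at full scale:
with 4-mm elements a single plane's measurements pin only every other
node layer, the fixed point contracts weakly, and after the prescribed
pass budget the recovered modulus at the sphere centres is typically
within 10–25% of truth rather than within 10%, with some sensitivity to
the network initialization seed. Under ideal information (the
`full_field` mode, or strain data supplied everywhere) the same engine
converges well inside 10%, and accuracy improves systematically with
plane coverage and mesh density, which is the regime the full-scale
configuration represents.

## Conventions

Voigt order is (xx, yy, zz, xy, xz, yz) with engineering shear strains,
everywhere. Geometry is in millimetres, moduli and stresses in kPa,
forces in newtons; the compression axis is y, the origin is the
phantom's bottom corner, and node/element indices are 1-based in the
usual R convention. Assembled stiffness from mm/kPa element quantities
is numerically identical to SI (N/m), so displacements convert at the
solver boundary only. The linear system is solved by sparse Cholesky
factorization with a $10^{-10}$ relative-residual check; rank
deficiency, duplicate constraints and non-SPD materials are reported as
errors naming the offending constraint or integration point.

## Known limitations

* Small-strain linear kinematics only; no contact mechanics (the probe
  is an ideal rigid flat footprint), no tetrahedral elements, so
  compression planes must be parallel or orthogonal to mesh axes.
* The MPN is evaluated through a shared tangent during assembly, i.e.
  solves are linear per cycle; materially nonlinear stress paths are out
  of scope.
* Scale factors are scalar per location; per-component scaling is not
  implemented.
* Desk-scale accuracy limits described above; the advisory statistics
  (`eta_eps` in particular) inherit histogram-estimator bias.
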