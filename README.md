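# autoprog

Quantitative elastic-modulus imaging for quasi-static ultrasound
elastography by the autoprogressive (AutoP) method.

A linear-array probe pressed a few millimetres into soft tissue yields,
per compression plane, the applied surface force *f*, the probe
displacement *u*, and speckle-tracked axial displacements *û<sub>y</sub>*
in the scan plane. `autoprog` turns such planar force–displacement
records into a volumetric, quantitative Young's-modulus map E(**x**)
(kPa). It is written for researchers in elasticity imaging and inverse
finite-element constitutive modelling who want a self-contained,
scriptable implementation with a matching synthetic-data generator.

## Method at its core

Two finite-element analyses run on a hexahedral mesh of the undeformed
volume: FEA<sub>σ</sub> applies the measured force through the rigid
probe footprint and produces a stress field σ(**x**); FEA<sub>ε</sub>
prescribes the measured displacements and produces a strain field
ε(**x**). The pairs (ε, σ) at the mesh integration points train a
Cartesian neural network constitutive model (CaNNCM),

σ(**x**, ε) = MPN( S(**x**) · ε ),

where the material property network MPN encodes the spatially averaged
stress–strain response and the spatial network SN encodes a strictly
positive strain scale factor S(**x**) capturing local deviations. The
trained model supplies the tangent stiffness for the next pair of
solves; cycles repeat over load steps and passes following a staged
multi-plane schedule (MPN first on one plane, then per-plane SN
training with a training-data history window, then all planes jointly).
Young's modulus is probed from the model tangent by a virtual
uniaxial-stress test, E = 1/C₂₂ with C the compliance. Three
information-theoretic statistics — stress entropy H(σ) (bits), strain
reversibility η<sub>ε</sub> (normalized mutual information between the
two solves' strains), and stress convergence Δσ̄ (kPa) — monitor
learning and drive a stop / acquire-more-data advisory.

A full account of the model, the numerics (under-relaxation of the
dual-FEA fixed point, identifiability anchors, estimator constructions)
and the design decisions is in `vignettes/autop-methods.Rmd`.

## Worked example

Simulate a homogeneous 32-mm gelatin cube (7.9 kPa), install the true
material as the constitutive model, and check that the force-driven and
displacement-driven solves agree perfectly on exact data:

```r
library(autoprog)

fx  <- standard_fixtures("homogeneous_desk")
sim <- simulate_fixture(fx)
sim$measurements
#> <plane_measurements> 1 plane(s) on a 32x32x32 mm mesh (h = 4 mm)
#>   z16: 3 steps, 27 footprint nodes, 81 measured nodes
sapply(sim$measurements$planes[[1]]$steps, function(s) round(s$f, 4))
#> [1] 0.0945 0.1890 0.2836        # newtons, linear in the 0.5 mm steps

truth <- cannccm_linear_isotropic(sim$mesh, 7.9, 0.45)
ss <- run_fea_sigma(sim$mesh, truth, sim$measurements, 1, 3)
se <- run_fea_epsilon(sim$mesh, truth, sim$measurements, 1, 3)
strain_reversibility(ss$strain, se$strain)
#> [1] 1                            # perfect agreement on exact data

img <- render_modulus(truth, sim$mesh,
  image_plane_spec(c(0, 0, 16), c(1, 0, 0), c(0, 1, 0), c(32, 32), 1))
img
#> <modulus_image> 32 x 32 px (1 mm/px); E range 7.9..7.9 kPa (0 missing)
autoplot(img)                      # ggplot2 heat map, kPa calibrated
```

The force values are the recorded reactions of the forward simulation
(0.28 N at 1.5 mm compression of the 32-mm cube); η<sub>ε</sub> = 1
means the strain distributions of the two solves are statistically
identical, the converged ideal. Training on a heterogeneous phantom is
one call:

```r
fx  <- standard_fixtures("two_sphere_desk")   # two 19.8 kPa spheres in 7.9 kPa gel
sim <- simulate_fixture(fx)
res <- run_schedule(sim$measurements, sim$mesh, seed = 1)
res$history                        # per-pass H(sigma), eta, delta-sigma-bar, advice
probe_youngs_modulus(res$model, rbind(c(11, 16, 12), c(21, 16, 20)))
```

A command-line interface wrapping the same functions ships in
`inst/cli/autoprog.R` (`simulate | train | stats | image | whatif`).

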