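# levatorfem

Quasi-static finite-element simulation of the levator ani muscle (LAM)
during the second stage of vaginal delivery, in R.

During birth the fetal head is driven through the pelvic floor and the
levator ani — the muscular diaphragm spanning the bony pelvis — undergoes
some of the largest deformations any human soft tissue experiences, with
stretch-related injury concentrated where the muscle arises from the pubic
bone. `levatorfem` is for biomechanics researchers who want a fully
synthetic, reproducible version of that analysis: every input (material
law, anatomy, head motion) is generated from published summary dimensions,
so the whole pipeline runs from code with no subject data.

The package provides:

* an N-term **Ogden hyperelastic material model** for passive LAM tissue,
  with strain energy
  `W = sum_ij (2 mu_j / alpha_j) (lbar_i^alpha_j - 1) + K/2 (J - 1)^2`
  (isochoric stretches `lbar_i = J^(-1/3) lambda_i`), the uniaxial nominal
  stress `P(lambda) = sum_j 2 mu_j (lambda^(alpha_j - 1) -
  lambda^(-alpha_j/2 - 1))`, full Cauchy stress, von Mises invariant, and
  the small-deformation stability check `sum_j mu_j alpha_j > 0`;
* constrained nonlinear least-squares **parameter identification** from
  uniaxial stress–stretch data (`fit_ogden()`, a classed model object with
  `coef`/`predict`/`plot`/`simulate` methods), plus a synthetic
  uniaxial-test generator;
* **parametric anatomy**: a fetal head ovoid and a bony pelvis that
  reproduce the standard obstetric diameters exactly at named landmarks,
  and a labelled tetrahedral levator shell (iliococcygeus, pubovisceral,
  puborectal regions; attachment, coupling and constraint node sets);
* a **cardinal-movements trajectory** for the head (descent along the
  curve of Carus, internal rotation, lateral straightening, extension
  hinging under the pubic symphysis) with exact net-motion bookkeeping;
* a **quasi-static Newton solver** with frictionless penalty contact
  against the rigid head, and per-region von Mises summaries, loading-order
  and mediosagittal-elongation reports.

## Worked example: identify the material, then simulate a delivery

```r
library(levatorfem)

# 1. the reference material, and a self-consistency fit to synthetic data
fit <- fit_ogden(generate_uniaxial_data(lam_material()), seed = 1)
coef(fit)
#>     mu1     mu2  alpha1  alpha2
#> 0.00008 0.00017 1.81000 17.25000

# 2. the prescribed head motion reproduces the configured net quantities
traj <- build_trajectory(trajectory_config(), head = build_fetal_head())
decompose_net_rotation(traj)
#>             extension     internal_rotation lateral_straightening
#>                 80.25                 40.13                 28.66

# 3. the full default simulation (about six minutes)
fem <- run_simulation(default_config(), out_dir = "delivery_run")
#> frame 47 reached only by relaxation; stopping with 46 equilibria
fem$elongation$max_stretch_ratio
#> [1] 1.147102
head(loading_order(fem$table), 3)
#>              region first_frame first_station
#> 1               ICm           4            -2
#> 2 posteromedial_PRm          16             0
#> 3  pubic_attachment          32             3
```

The run writes a results directory with the per-station regional stress
table (`stress_table.csv`, the mean/min/max/SD of element von Mises stress
in the iliococcygeus, the left pubic-attachment zone and the posteromedial
puborectal sling), an elongation report (`elongation.json`), the head
trajectory, VTK snapshots of the deformed shell, rigid-surface OBJ files,
solver diagnostics and a manifest. The iliococcygeus is the first region
to load (station −2, just after engagement), the global von Mises maximum
sits in the pubic-attachment zone, and the pubic mean peaks at the onset
of extension — the structural pattern of the published analysis. The
simulation ends, by default, at the last strictly converged equilibrium
(about 15° into extension at the default resolution): beyond that point
the rigid head pinches tissue against the fixed pubic attachment with no
finite-gap solution, so later states could only be produced by relaxation
and are not reported. The printed maximal mediosagittal stretch ratio
(1.15) therefore understates the published full-delivery elongation of
about 2.5, which occurs at maximal distension late in extension; see the
methods vignette for the full discussion.

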