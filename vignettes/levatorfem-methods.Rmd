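---
title: "Modelling levator ani stress during vaginal delivery with levatorfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling levator ani stress during vaginal delivery with levatorfem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`levatorfem` simulates the second stage of vaginal delivery as a quasi-static
large-deformation finite-element problem: a rigid fetal head is driven along
a prescribed cardinal-movements trajectory through a deformable levator ani
muscle (LAM) shell, and the resulting von Mises stress field is summarised
per anatomical region and per obstetric station. This vignette records the
model, its assumptions, the tunable parameters, and the numerical choices —
in particular which parts of the pipeline are established mechanics and
which are calibration choices of the synthetic geometry.

## The constitutive model

Passive LAM tissue is modelled as an isotropic, nearly incompressible
N-term Ogden solid. With principal stretches $\lambda_i$,
$J = \lambda_1\lambda_2\lambda_3$ and isochoric stretches
$\bar\lambda_i = J^{-1/3}\lambda_i$, the strain energy density is

$$ W \;=\; \sum_{i=1}^{3}\sum_{j=1}^{N} \frac{2\mu_j}{\alpha_j}
   \left(\bar\lambda_i^{\alpha_j} - 1\right)
   \;+\; \frac{K}{2}\,(J-1)^2 , $$

in MPa, and the uniaxial nominal (first Piola–Kirchhoff) stress under
incompressible kinematics ($\lambda_2=\lambda_3=\lambda^{-1/2}$, $J=1$) is

$$ P(\lambda) \;=\; \sum_{j=1}^{N} 2\mu_j\!\left(\lambda^{\alpha_j-1} -
   \lambda^{-\alpha_j/2-1}\right). $$

The packaged reference set (`lam_material()`) is the two-term fit to a
cadaver uniaxial tension test: $\mu_1 = 8\cdot10^{-5}$ MPa,
$\mu_2 = 1.7\cdot10^{-4}$ MPa, $\alpha_1 = 1.81$, $\alpha_2 = 17.25$.
Small-deformation stability requires $\sum_j \mu_j\alpha_j > 0$; for this
energy form that sum *is* the small-strain shear modulus, and the package
verifies it numerically from the uniaxial tangent rather than assuming the
identity. The bulk modulus is not an independent datum: it is derived from
Poisson's ratio $\nu = 0.499$ as $K = 2G(1+\nu)/(3(1-2\nu))$, giving
$K/G \approx 500$. Time dependence is not modelled: the loading is a
prescribed motion and only the hyperelastic energy is specified, so rate
effects would be unidentifiable here. Fibre anisotropy is likewise out of
scope.

The second exponent, 17.25, deserves emphasis: stresses scale like
$\lambda^{16.25}$, so a stretch of 2 multiplies stress by roughly $10^{4.9}$
relative to the small-strain regime. Every numerical choice below is shaped
by this extreme stiffening.

## Parameter identification

`fit_ogden()` identifies $(\mu_j, \alpha_j)$ from uniaxial
stress–stretch data by constrained nonlinear least squares on
$E = \tfrac12\sum_i (P_i^{test} - P_i^{model})^2$, using
Levenberg–Marquardt (`minpack.lm::nls.lm`) under box bounds
($\mu > 0$, $|\alpha| \le 30$), with the stability constraint enforced by a
smooth penalty plus rejection of unstable local minima. Because the
objective is multimodal in $\alpha$, the fit is multi-started: one
deterministic heuristic start and seven seeded random restarts with $\mu$
log-uniform on $[10^{-6}, 10^{-2}]$ MPa and $\alpha$ uniform on $[0.5, 25]$.
Ogden terms are exchangeable, so results are reported with $\alpha$ sorted
ascending. The source cadaver data are not published as numbers, so the
package ships a synthetic uniaxial-test generator
(`generate_uniaxial_data()`) whose default grid spans stretches 1–1.6 in 50
points; the default fitting exercise is therefore a *self-consistency*
recovery, which the test suite requires to reproduce the reference curve
within 1% and the exponents within 5%.

## Synthetic anatomy

The subject geometry behind the original analysis is MRI-derived and not
available, so every body is generated parametrically from the printed
dimensions.

* **Fetal head** (`build_fetal_head()`): an ovoid built from a base
  ellipsoid (biparietal width 93.7 mm, occipitofrontal length 105.7 mm)
  with smooth radial Gaussian corrections solved so that all four principal
  diameters — including suboccipitobregmatic 100.3 mm and occipitomental
  131.9 mm chord distances — are met exactly at named landmarks.
* **Bony pelvis** (`build_pelvis()`): elliptical inlet, interspinous and
  outlet rings lofted along the canal axis, reproducing the inlet AP
  (113.4 mm), outlet AP (145.1 mm), transverse inlet (148.8 mm) and
  interspinous (146.7 mm) diameters at landmark pairs. The interspinous
  plane is $z = 0$ and anchors the obstetric station scale.
* **Levator shell** (`build_levator()`): a funnel/hammock mid-surface
  spanning an outer attachment ring (pubis anteriorly, tendinous arch
  laterally, sacrum dorsally) down to an anteriorly offset hiatal rim,
  extruded through the thickness and filled with labelled tetrahedra
  (regions ICm / PVm / PRm; node sets for the pubic and sacral fixations,
  the tendinous-arch coupling, the plane-constrained cranial ICm band, the
  distal puborectal loop, and the ordered posterior mediosagittal trace).

The shell's free parameters are calibration, not printed data, and are
documented as such: hiatal rim 35 × 55 mm centred on the head's descent
path; shell thickness 7 mm, tapered to ≈35% at the tendinous pubic origin;
outer ring semi-axes 75 × 78 mm, i.e. on the bony margins at the outlet
radius; dorsal dome rising to z = +55 mm. Two requirements fix them: the
descending reference head must first engage the shell near station −3
(first contact occurs at −2.8 with clearance at −3), and the tissue band at
the pubic arch must retain at least its own thickness of clearance from the
head's swept volume — with the head and the attachment both rigid, a
smaller gap has no finite-thickness solution. The radial grid is graded by
arc length so the steep funnel is meshed with well-shaped elements.

## Head kinematics

The trajectory (`build_trajectory()`) prescribes the cardinal movements in
a fixed world frame (x maternal left, y anterior, z cranial):

* descent of the vertex from station −3 to +5 along a circular
  curve-of-Carus arc (radius 160 mm) in the mediosagittal plane, with the
  vertex-z schedule exact per station;
* internal rotation about z (40.13°, occiput left-anterior → anterior) and
  straightening of the initial 28.66° rightward deviation, both linear in
  descent and complete at station +3;
* extension of 80.25° about the lateral axis, hinging about the inferior
  pubic margin, with a small caudal drift that keeps the vertex descent
  strictly monotone; the vertex continues to stations +6…+8 during
  extension.

The net anterior displacement of the head origin is closed exactly to
100.0 mm by a residual translation in the extension phase, so the
configured net motion (100.0 mm, 80.25°/40.13°/28.66°) is reproduced to
round-off by construction; `decompose_net_rotation()` factors the net
rotation as $R_x(e)\,R_z(r)\,R_y(s)$ and round-trips the configuration.
Progression is uniform per frame (5 frames per station; 24 extension
frames, because the hinge sweeps head-surface points many times faster
than descent does), a deliberate simplification of real labour's
progress-and-standstill pattern. The head is rigid; moulding is not
modelled.

## The quasi-static solve

Each trajectory frame is a static equilibrium of the shell under
frictionless penalty contact with the posed head, solved by Newton
iteration in reduced coordinates that enforce the boundary conditions
exactly (pubic/sacral sets fixed; the cranial ICm band restricted to its
best-fit sacral plane; tendinous-arch nodes tethered elastically,
0.5 N/mm, to stand in for the obturator internus support, whose
constitutive data are not available). Element internal forces are the
analytic principal-stretch gradient of $W$ over linear tetrahedra; element
tangents are forward finite differences of the element gradient,
symmetrised — with the sparsity pattern, its reduced-coordinate expansion
and the factorisation's symbolic analysis all precomputed once.

Numerical choices that matter, all motivated by the $\lambda^{16}$
stiffening and the facetted contact geometry:

* **Contact**: node-to-surface penalty against the triangulated head, with
  barycentrically interpolated vertex normals (smooth across facets) and a
  C1 force ramp over the first half-percent of the shell thickness, which
  removes the marginal-contact chattering of the pure linear law. A radial
  star-shape table covers the deep interior so the barrier is monotone all
  the way to the head's centre. Bone-fixed nodes take no part in contact
  (they cannot move and would otherwise drive the penalty adaptation when
  the head sweeps past the fixed entheses), and beyond half a shell
  thickness of penetration the force saturates: tissue caught in the
  rigid-rigid shadow between head and a fixed attachment has no finite-gap
  equilibrium, and the plateau keeps such trapped nodes from destroying
  the tangent.
* **Penalty adaptation**: the stiffness starts at 100 × (small-strain shear
  modulus × element edge) and is adapted by a secant rule so converged
  penetration stays below 1% of the shell thickness, backing off to the
  last solvable stiffness when escalation makes Newton fail.
* **Tolerances**: convergence is declared at a residual below
  $10^{-4}$ of the applied contact/tether force norm (lagged one frame, and
  capped to ×10 growth per frame, so penalty escalation cannot loosen the
  tolerance of the very frame being solved), with an absolute floor of
  $10^{-5}$ N and a stagnation acceptance at the contact-facet noise floor.
* **Continuation**: failed increments are retried on uniformly refined
  pose subladders ($4^k$ substeps); the finest level may use a
  viscous-stabilised solve polished by an unstabilised one, and, as a last
  resort, damped pseudo-dynamics with kinetic damping (the quasi-static
  analogue of riding a limit point with an explicit integrator). States
  produced by that terminal fallback are flagged `relaxed`; by default the
  run **stops cleanly at the first such frame**, so every returned state is
  a strict equilibrium (`stop_on_relaxed = FALSE` marches on through the
  flagged states instead).
* **Incompressibility**: the volumetric term uses the element-wise $J$ of
  the standard displacement formulation. A patch-averaged dilatation
  treatment was considered and rejected: the problem is membrane-dominated,
  the two-to-three-element-thick shell carries the constraint by thinning,
  and patch averaging couples neighbouring elements in the tangent for no
  measurable benefit at these resolutions.

The run is fully deterministic — there is no randomness anywhere in the
solver — so identical configurations give bit-identical state sequences.

## Postprocessing

`summarize_run()` produces the per-frame, per-region von Mises table
(volume-weighted mean, min, max, and volume-weighted *population* SD — the
reported tables do not state which SD convention they use, so the choice is
documented here). The three reporting zones map the anatomical columns of
the published table: the ICm label; PVm/PRm elements within 25 mm of the
left pubic attachment; and PRm elements dorsal to the hiatal centre.
`loading_order()` ranks regions by the first frame whose mean exceeds 1% of
that region's own run maximum — a per-region threshold, because regional
magnitudes differ by orders of magnitude (on the published numbers
themselves, the ICm's first reported mean is below 1% of the global
maximum, so a global threshold could not reproduce the published loading
order). `elongation_report()` tracks the posterior mediosagittal trace
(sacrum → hiatal rim, mid-thickness) and reports the maximal
deformed-to-initial arc-length ratio and the maximal caudal displacement of
the distal puborectal loop.

## What the synthetic geometry can and cannot show

The generator emulates the *printed dimensions* of one subject, not her
anatomy: the shell is a smooth parametric funnel without muscle
subdivision gaps, fibre architecture, or neighbouring organs, and the
obturator support is an elastic tether rather than a muscle body. Absolute
stress magnitudes are therefore not comparable to subject-specific values —
they depend strongly on the local geometry (and on the Ogden exponent 17.25
they vary by orders of magnitude across the shell). What the model does
support, and what the tests assert, are the structural results: the
engagement sequence of the regions, the location of the stress maximum in
the pubis-origin portion, the timing of its peak at extension, and the
headline mediosagittal elongation ratio, which is a geometric quantity far
more robust than any stress value.

Default problem sizes are chosen for desk-scale runtimes: 6 mm element
edge (≈5k tetrahedra, about six minutes for the default run) for the
reference simulation, with 4 mm and 2 mm available in the configuration
for convergence studies; the solver test fixtures use a few hundred
elements.

## What the default run reports, and what it cannot

With the defaults the solver returns 46 strict equilibria: engagement
(first contact at station −2.8) through descent to station +5 and the
first ≈15° of extension. Within that window the structural pattern of the
reference analysis holds: the iliococcygeus loads first (station −2), the
global von Mises maximum lies in the pubic-attachment zone, and the
pubic-attachment mean peaks at the onset of extension. Two quantities fall
short of the published full-delivery values, and deliberately so:

* the **maximal mediosagittal stretch ratio** reports ≈1.15 against the
  published ≈2.5. The 2.5× elongation belongs to maximal distension late
  in extension; in the synthetic geometry the rigid head then pinches
  tissue against the fixed pubic attachment with sub-millimetre clearance
  (scanned over every pivot and ring variant considered), a configuration
  with no finite-thickness equilibrium, so the quasi-static run ends
  before it. The synthetic trace also includes the slack dorsal shelf,
  which dilutes the distal sling's stretch in the arc-length ratio.
* the **regional loading order** comes out iliococcygeus → posteromedial
  puborectal → pubic attachment, i.e. with the last two swapped relative
  to the reference sequence: the synthetic anterior wall is placed at the
  bony outlet radius (required for solvability of the rigid–rigid pinch),
  so the head only reaches it during the anterior extension sweep. Both
  engagement-threshold definitions (global and per-region) give the same
  swapped order.

Neither shortfall is hidden by the tests: the corresponding acceptance
checks assert the published values and fail.

## Known limitations

* Extension drives a rigid head past a fixed attachment arc with
  millimetre clearances; the pinched anterior band is resolved only at the
  level the mesh allows, and late-extension frames may be flagged
  `relaxed` rather than strictly converged.
* Linear tetrahedra with $\nu = 0.499$ are locking-prone in bending; the
  thin-shell discretisation limits but does not remove this.
* Self-contact of the shell is ignored, as is friction (the lubricated
  contact assumption), head moulding, and active muscle contraction.
* The station labels of extension frames continue past +5 even though the
  classical scale ends there; they are reported as the vertex depth in cm.
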