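---
title: "From impact biomechanics to white-matter pathology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From impact biomechanics to white-matter pathology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ccistrain` reproduces, at desk scale, a computational pipeline linking the
biomechanics of a controlled cortical impact (CCI) on the rat brain to
white-matter injury measures. The chain is:

1. a voxel-label **brain phantom** (grey matter, white-matter callosal band,
   CSF, ventricles, dura surface, skull with a craniotomy window);
2. **image-based hexahedral meshing** with restricted surface smoothing;
3. an **explicit-dynamics finite element solve** of a rigid flat-cylinder
   impactor driven at constant velocity to a 1 mm (mild) or 2 mm (moderate)
   indentation, with a nearly incompressible hyper-viscoelastic tissue
   model;
4. reduction of the deformation history to the per-element maxima of
   **first principal Green-Lagrange strain** and its time derivative
   (**strain rate**, 1/ms), threshold-exceedance volume fractions, and
   five-segment **corpus-callosum summaries** per hemisphere;
5. a **synthetic outcome generator** that plants strain relationships in
   per-animal, per-segment imaging and histology measures; and
6. **linear mixed-effects models** of injury change on strain or strain
   rate, with Nakagawa marginal R², leave-one-animal-out predictive R²,
   backward selection and residual diagnostics.

Everything runs from one config via `run_all()`; the pieces are ordinary
exported functions.

# The phantom and what it stands for

The phantom replaces a licensed rat atlas with analytic geometry carrying
the same tissue classes. Defaults: a superellipsoidal brain with half-axes
7 x 9 x 4.5 mm, quartic in the lateral (x) direction — the coronal profile
is flat dorsally and falls away laterally, like a rat coronal section, so
a flat impactor engages it progressively with depth (the source of the
strong growth of peak force from 1 mm to 2 mm indentation); the crown
above z = 4.4 mm is clipped. Around it: 0.5 mm CSF, a one-voxel dura
surface, 1 mm rigid skull, a 6 x 7 mm craniotomy window centred ~3.5 mm
lateral of the midline, paired ventricles, and an arched callosal band
(0.8 mm thick, apex 1.5 mm below the dorsal crown, arch drop 0.06 mm per
mm² lateral, |y| <= 2 mm, |x| <= 5 mm). The default resolution is 0.5 mm —
about 11000 brain hexahedra — not the 0.16 mm of a full-scale model;
resolution is a parameter and every geometric feature is testable against
brute-force voxelisation. The coronal profile matters: with a fully flat
dorsal cap the punch is completely engaged from first contact and the
mild/moderate force ratio collapses toward 2; with an untruncated
ellipsoid the surface drops 1.7 mm across the footprint and a 1 mm
indentation barely loads the brain.

Coordinates: 0-based voxel indices; world = origin + index x voxel size
(voxel centres); x is left-right (impact side x > 0), y
anterior-posterior, z dorsoventral.

# Meshing and smoothing

One hexahedron per selected voxel with shared corner nodes; dura membranes
(20 um shells) on boundary faces adjoining dura/skull labels; the skull is
realised as fixed (rigid, immobile) boundary nodes except inside the
craniotomy window. Surface smoothing is restricted to the outer surface and
the CSF/cortex interface, as Taubin shrink/inflate passes (inflate step
lambda / (0.1 lambda - 1)) rather than plain Laplacian smoothing: on a
voxel cube, five plain Laplacian passes at relaxation 0.5 shrink the volume
by ~15%, whereas the Taubin variant keeps the change well under 1%, which
matters because element volumes weight every downstream exceedance
fraction. The pipeline smooths the phantom with relaxation 0.2 (five
iterations): the CSF layer is a single voxel thick at desk resolution and
stronger steps invert elements — the positive-Jacobian guard aborts rather
than accepting a tangled mesh.

# Constitutive model

Deviatoric response: Ogden principal-stretch hyperelasticity on the
isochoric stretches; volumetric response: penalty `K (J - 1)`; time
dependence: a Prony shear-relaxation series applied to the deviatoric
stress by the standard recursive exponential update, so a step shear decays
along `G(t)/G0` exactly. `G0 = sum(mu_i alpha_i)/2`; the Prony weights are
relative to `G0` and `G_inf = (1 - sum g_k) G0`. Species scaling multiplies
every shear modulus by the ratio of long-term moduli
(`scale_relaxation()`), leaving time constants untouched.

Defaults (grey = white, as the underlying rat/human indentation data do not
separate them): single-term Ogden with `alpha = 4`, `mu = 0.005` MPa (so
`G0 = mu alpha / 2` = 10 kPa), Prony `g = (0.5, 0.3)`,
`tau = (0.08, 0.8)` ms, i.e. `G_inf` = 2 kPa — a rodent-scale long-term
cortical stiffness; density 1.04e-3 g/mm³. The published constants for
this model live in supplementary material that is not redistributed here,
so the default is a documented stand-in: `alpha = 4` carries the strain
stiffening that Ogden fits of brain tissue usually show (|alpha| of a few
to ~10), while even exponents keep the solver's deviatoric stress in
closed polynomial form (`mu dev(b̄^(alpha/2))/J`, no per-element
eigensolve). The material module itself supports arbitrary Ogden
exponents through the principal-stretch route, and all constitutive tests
are parameter-generic. CSF and ventricles use the same framework with
shear moduli 100x lower (soft-solid CSF) and the same bulk modulus.

Two bulk-modulus profiles exist: `"desk"` (K = 50 MPa) and
`"physiological"` (K = 2000 MPa). The desk profile trades strict
incompressibility for an order-of-magnitude larger stable time step; the
consequences are quantified below.

Units are g-mm-ms throughout: stresses in MPa, forces in N, densities in
g/mm³, times in ms.

# The explicit solver

Central-difference (leapfrog) integration with single-point-integration
hexahedra, Flanagan-Belytschko hourglass shape vectors with viscous
control, standard linear-plus-quadratic bulk viscosity in compression
(capped at 3K), and lumped mass. The time step is
`dt_safety x min(L_e / c_e)` with `L_e` = volume over largest face area and
`c_e` the dilatational wave speed; the default safety factor is 0.45
because smoothing-distorted boundary elements and the contact springs
consume part of the nominal margin.

The impactor is an analytic rigid flat-ended cylinder descending along -z
at constant velocity (after a 0.01 ms velocity ramp that regularises the
initial acceleration) until the commanded depth, then held. Contact is a
node-to-analytic-surface penalty with critical-ratio damping against the
**closest feature** of the solid — flat face, rim fillet (default radius:
one element edge), or side wall — so nodes that drift under the rim are
expelled along the nearest exit instead of being slammed down by the face
plane. A face-only contact, tried first, produced exactly that slamming:
surface nodes oscillating across the footprint radius acquired finite
penetrations in one step, and the resulting impulses pumped energy into
the mesh indefinitely. The closest-feature formulation closes the energy
ledger (external work vs kinetic + internal + hourglass + contact terms)
to a few percent on erosion-free runs.

Two mechanisms deal with the extreme local deformation a blunt 1-2 mm
indentation forces onto a 0.5 mm mesh:

* **Element erosion.** Elements volumetrically crushed below `J = 0.15`
  or isochorically stretched beyond a principal stretch of 3 are
  deactivated — physically, the thin CSF film being expelled from under
  the punch and the rim shear band where tissue integrity is lost (the
  same region the in vivo data map as contusion). Their strain history is
  frozen at the erosion time; nodes whose incident elements have all
  eroded are retired. Erosion deliberately removes stressed material, so
  runs with substantial erosion do not conserve energy exactly; the
  ledger flags report this.
* **Selective mass scaling.** Every ten steps the current critical time
  step of each element is re-estimated from its deformed geometry
  (`L ~ V0 J / A_max`, `c ~ c_ref sqrt(J)`); elements falling below the
  run step receive added nodal mass, as in standard explicit codes. The
  added-mass fraction is reported (`mass_added_frac`) and stays small for
  the mild impact.

Hourglass work can exceed 10% of the *stored* internal energy at the end
of a run even when the solution is clean: the tissue is almost purely
elastic at these time scales, so most input work is returned through the
contact interface and the stored internal energy at the end is near zero,
which makes the ratio ill-conditioned. The check is therefore reported as
a flag on the result rather than an error.

# Strain metrics

Per element and snapshot (0.01 ms), the first principal Green-Lagrange
strain is the largest eigenvalue of `(F'F - I)/2` (vectorised
trigonometric eigensolve); the field keeps the per-element maximum over
time, following the convention of maximum-over-history injury metrics.
"Strain rate" is read as the central finite difference of the principal
strain series — the common injury-biomechanics reading — with the
alternative (principal value of the rate-of-deformation tensor) behind
`rate_method = "rate_tensor"`. Exceedance volume fractions use grey +
white elements only (CSF and ventricles excluded from numerator and
denominator); whether "brain volume" includes CSF-filled elements is a
convention, and this one is fixed and documented here.

# Corpus-callosum segments

The callosal mask is one coronal plane of white-matter voxels. Each
hemisphere is ranked by within-mask geodesic (8-connected, in-plane)
distance from the midline and cut into five contiguous groups of equal
voxel count — "equal" is read as equal count rather than equal arc length;
with a remainder, the extra voxels go to the more medial segments (23
voxels give 5,5,5,4,4). Segment 1 is midline-adjacent, segment 5 most
lateral. Elements map to segments through their source-voxel identity
(recorded at meshing, so smoothing cannot detach them), avoiding
point-in-mesh searches.

On the default phantom the mild-impact ipsilateral strain profile peaks in
segments 3-4 (under the impactor) and the contralateral profile peaks in
segment 1, as expected. In the moderate run the most lateral ipsilateral
segment sits inside the rim shear band where erosion-scale strains occur,
so its mean is dominated by tissue-failure-scale values; the mild run is
the clean probe of the spatial pattern.

# Synthetic outcomes and their calibration

The generator plants
`value = baseline + beta_strain strain + (beta_severity +
beta_interaction strain) 1[moderate] + a_animal + s_segment + eps`
with Gaussian components, identity or log link, one row per (animal,
hemisphere, segment, measure); contralateral rows carry baseline plus
random effects only. Changes are computed either against the same
animal's contralateral segment (diffusion convention) or against the
contralateral group mean (histology convention, used with the 100%
contralateral normalisation).

Effect sizes and variance components are exactly what the original
analysis estimates, so they cannot be taken from it as inputs; the
defaults are instead calibrated so that the strain-only mixed model on a
unit-variance standardised strain covariate has a planted marginal R² of
0.33 for the FA-like measure (slope -1, animal SD 0.8, residual SD
1.1791) and 0.51 for the microglia-density measure (slope +1, animal SD
0.8, residual SD 0.566). What parameter-recovery tests then show is that
the estimation machinery is unbiased at those values — not that real
tissue behaves this way. The generator also omits, deliberately: spatial
correlation between neighbouring segments beyond the shared intercepts,
non-Gaussian measurement error, censoring/dropout, and any nonlinearity
in the strain-outcome relationship.

The glial table plants process thicknesses straddling the 2.7 um
activation rule; classification is strict (`> 2.7`), so a cell at exactly
2.7 um is not activated.

# Mixed-effects stage

`fit_lme()` is a REML random-intercept fit (crossed animal and segment
intercepts by default; "animals and segments as random effects" is read
as crossed, with nesting available by dropping a term). Strain and strain
rate are never allowed in one model without an explicit override — their
correlation across segments is ~0.96, and the collinearity diagnostic
uses |r| > 0.9 for the same reason. Marginal R² is the Nakagawa ratio
Var(fixed predictions) / (Var(fixed) + sum of variance components).
Predictive R² is leave-one-*animal*-out PRESS (animals are the
exchangeable unit; "predicts future data" means a new animal), predicted
from fixed effects only; it can be negative and is flagged rather than
clipped. Backward selection drops, at each stage, the term whose removal
least degrades predictive R², stopping when degradation would exceed 0.01,
with the interaction always leaving before its main effects; an AIC
criterion is available behind a flag. Diagnostics: Shapiro-Wilk on
residuals, a t-test on the slope of |residual| vs fitted, pairwise
covariate correlations; a failed check suggests the log transform
(`apply_log()`, automatic positive shift).

Numerical notes: non-convergent fits return a status so selection can skip
them; singular fits (zero variance components on noise-free data) are
accepted and flagged; REML invariance to location shifts and marginal-R²
invariance to outcome scaling are tested properties.

# Problem sizes used by the tests and the acceptance script

The bundled checks run the full-resolution (0.5 mm) phantom for the two
acceptance simulations, and a 1 mm phantom (~1100 brain hexes) for the
solver property tests, with smoothing 5 x 0.2 in both. Statistical
recovery runs use 400 animals x 5 segments x 20 replicates for the
marginal-R² targets and smaller designs (6-40 animals) for exactness and
selection properties. These sizes are the package's desk-scale choices;
all of them are parameters.

# Known limitations

* The phantom is an idealisation: no gyri (the rat is lissencephalic, so
  this is mild), no brainstem/cerebellum, a parabolic-arch callosum, and
  a flat dorsal cap.
* The desk bulk modulus (50 MPa) leaves the tissue measurably more
  compressible than brain. The mild-to-moderate peak-force ratio is driven
  mainly by progressive engagement of the flat punch on the curved dorsal
  surface, which is why the coronal profile of the phantom (flat dorsally,
  falling away laterally) matters more than the bulk modulus for that
  quantity.
* Peak contact forces are read from a low-pass-filtered force history
  (0.05 ms moving average, the standard treatment of impact force
  channels): the raw penalty history carries a sub-resolution engagement
  spike at first touch whose height reflects the contact stiffness and
  surface-voxel mass rather than tissue response.
* Erosion and mass scaling are numerical surrogates for physical
  processes (CSF expulsion, tissue failure) that a 0.5 mm mesh cannot
  resolve; their thresholds are config and their effects are reported per
  run.
* The white matter is mechanically isotropic and identical to grey, by
  design.
* Mixed-model p-values are out of scope; the interest is in effect sizes
  and R² measures.
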