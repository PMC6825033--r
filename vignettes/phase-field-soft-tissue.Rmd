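---
title: "Anisotropic crack phase-field modelling of fibrous soft tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic crack phase-field modelling of fibrous soft tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrocrack)
```

## The model

`fibrocrack` simulates progressive damage and rupture of fibre-reinforced
soft biological tissue — the motivating application is the incipient
propagation of an aortic dissection — with a crack phase-field approach at
finite strains.  Two primary fields live on the body: the deformation map,
and a scalar crack phase field $d \in [0,1]$ interpolating between intact
($d=0$) and ruptured ($d=1$) material over a regularisation length scale
$l$, so that a sharp crack surface is replaced by the volume integral of a
crack surface density.

**Elasticity.**  The effective (undamaged) energy is the
Holzapfel–Gasser–Ogden form with an isotropic ground matrix plus two
exponential collagen-fibre families with mean reference directions
$\mathbf{M}, \mathbf{M}'$ at $\pm\alpha$ to the circumferential direction:

$$
\Psi_0^{\mathrm{iso}} = \tfrac{\mu}{2}(I_1 - 3 - 2\ln J)
  + \tfrac{\kappa}{4}(J^2 - 1 - 2\ln J), \qquad
\Psi_0^{\mathrm{ani}} = \tfrac{k_1}{2k_2}\sum_{i=4,6}
  \left[e^{k_2\langle I_i-1\rangle^2} - 1\right],
$$

with $I_1 = \operatorname{tr}\mathbf{b}$, $J = \det\mathbf{F}$ and the
squared fibre stretches $I_4, I_6$.  The Macaulay bracket implements
tension-only fibres: whether shortened fibres should store energy is not
settled for arterial tissue, so the switch is exposed
(`solver_settings(tension_only = )`) with tension-only as the default, the
standard convention for this model class.  Coordinates are Cartesian and
both metric tensors are absorbed as identities.

**Degradation.**  Damage degrades the stored energy through
$g_i(d) = (1-d)^{a_i}$ applied separately to the isotropic and anisotropic
parts; the exponents default to the quadratic $a_{\mathrm{iso}} =
a_{\mathrm{ani}} = 2$.  The Kirchhoff stress and the consistent spatial
tangent follow in closed form (`kirchhoff_stress()`,
`material_tangent()`); both are cross-checked against finite differences of
the energy in the test suite.

**Crack geometry and anisotropy.**  The regularised crack surface density is
$\gamma = \frac{1}{2l}(d^2 + \nabla d\cdot\boldsymbol{\mathcal L}\nabla d)$
with the structure tensor
$\boldsymbol{\mathcal L} = l^2(\mathbf{I} + \omega_M \mathbf{M}\otimes\mathbf{M}
+ \omega_{M'} \mathbf{M}'\otimes\mathbf{M}')$.
The anisotropy parameters $\omega_i \in (-1,\infty)$ penalise phase-field
gradients along the fibres, so that for large $\omega$ the crack is forced
to run parallel to the fibre direction; $\omega = 0$ recovers the isotropic
density, and the lower bound is the ellipticity limit that
`phase_field_params()` enforces.

**Failure criterion and evolution.**  Cracking of the ground matrix and of
the fibrous content are treated as distinct processes with separate critical
fracture energies, entering through the dimensionless driving sources
$\bar{\mathcal H}^{\mathrm{iso}} = \Psi_0^{\mathrm{iso}}/(g_c^{\mathrm{iso}}/l)$
and
$\bar{\mathcal H}^{\mathrm{ani}} = \Psi_0^{\mathrm{ani}}/(g_c^{\mathrm{ani}}/l)$.
Because only the ratio $g_c/l$ ever enters, it is configured directly
(`gc_iso_over_l`, `gc_ani_over_l`), with $l$ set separately against the mesh
resolution rule $l > 2h$.  The *effective* energies drive failure — the
criterion does not weaken as the material degrades — and the volumetric part
of $\Psi_0^{\mathrm{iso}}$ is included in the driving energy (configurable
conceptually, but the tube study keeps it; see below for what *is* changed
there).  Irreversibility comes from the history field
$\mathcal H(t) = \max_{s\le t}\langle \bar{\mathcal H}(s) - 1\rangle$:
the Macaulay bracket keeps the solid intact until the failure surface
$\bar{\mathcal H} = 1$ is crossed.  Superposing the two failure processes
gives the evolution equation

$$
\eta\,\dot d = (1-d)\,\mathcal H
  - \left[d - \tfrac{1}{2}\operatorname{Div}(\boldsymbol{\mathcal L}\nabla d)\right],
$$

whose rate-independent limit ($\eta = 0$, the default — the studies never
state a viscosity) has the homogeneous solution $d = \mathcal H/(1+\mathcal H)$
used as an analytic oracle.  Note the factor $\tfrac12$ on the divergence
term: it is a consequence of superposing the matrix and fibre criteria, and
it means the steady clamped-crack profile of the *evolution* operator is not
the optimal profile $e^{-x/l}$ of the *geometric* crack equation
$d - \operatorname{Div}(\boldsymbol{\mathcal L}\nabla d) = 0$.  The package
exposes both: `solve_phasefield()` advances the evolution equation, while
`solve_crack_profile()` solves the geometric equation (and reproduces
$e^{-x/l}$ with second-order convergence in the tests).

## Discretization and the staggered solver

Standard displacement-based elements with full integration: 4-node
quadrilaterals (2×2 Gauss) in plane strain and 4-node tetrahedra (1-point)
in 3-D, for both fields.  Each pseudo-time increment applies a **one-pass
operator split**: (1) Newton solve of the balance of linear momentum at
frozen $d$, in updated-Lagrangian form with the Kirchhoff stress and the
consistent spatial tangent; (2) update of $\mathcal H$ at the quadrature
points from the converged effective energies; (3) one linear, symmetric
positive definite solve for the nodal phase field.  There is no
sub-iteration; the scheme is robust but slightly under-predicts the crack
speed, which is why the notched-plate study uses many small increments (see
below).  The solver is fully deterministic.

Numerical choices that matter:

* **Newton and step control.**  Convergence requires the free-dof force
  residual to drop below `max(atol·(1+|f_ext|), rtol·r0)` with
  `rtol = 1e-8`.  Failure halves the increment down to `dt_min` (defaults
  `dt = 1e-2` to `dt_min = 1e-4`, mirroring the reference loading protocol);
  exhaustion ends the run at the last converged state with a diagnostic
  rather than an error.
* **Linear solves.**  The mechanics tangent is symmetric except for the
  follower-pressure load stiffness (relative asymmetry ~1e-4), so the Newton
  direction uses a sparse Cholesky of the symmetrised tangent (about 20×
  faster than sparse LU at these sizes), falling back to LU when the tangent
  is indefinite.  The phase-field system is SPD and solved directly.
* **Residual stiffness.**  Inside the solver the degradation functions are
  offset by `resid_stiff` (default 1e-6) so fully broken elements keep an
  invertible tangent.  The exported constitutive functions use the exact
  $g(d)$, so $\boldsymbol\tau(d{=}1) = \mathbf 0$.
* **Irreversibility projection.**  After each linear phase-field solve the
  nodal field is projected onto $[d_n, 1]$.  The history field already
  enforces irreversibility of the driving source; the projection removes
  O(1e-6) discretization undershoots of the consistent-mass system so that
  the bounds $d\in[0,1]$ and per-step monotonicity hold exactly.
* **Follower pressure.**  Inner-surface pressure acts on the current
  configuration through oriented surface triangles; the load-stiffness term
  is included in the tangent, which matters at the supra-physiological
  600 mmHg inflation.

## Parameter identification

The four experimental modes — in-plane simple shear on the radial plane
along the circumferential and axial directions ($r\theta$, $rz$), and
uniaxial extension in both in-plane directions ($\theta\theta$, $zz$) — have
closed-form homogeneous responses under full incompressibility
(`model_stress()`).  Because both fibre families lie in the
$\theta$–$z$ plane, the in-plane shear modes leave them unstretched and
respond with slope $\mu$; the uniaxial modes carry the fibre information,
with the lateral stretch solved from the traction-free condition.  The
identification minimises the unweighted sum of squared Cauchy-stress
residuals pooled over all modes with a bounded Levenberg–Marquardt search
(`minpack.lm`), a deterministic five-start multistart (ties broken by the
smaller $k_2$), and reports per-mode $R^2$ and the normalised
root-mean-square error
$\epsilon = \sqrt{\chi^2/(N - q)} \,/\, \sum_{(ij)} \bar\sigma^{\mathrm{mean}}_{(ij)}$
with $q = 4$ parameters.

Since the underlying experimental curves are not deposited,
`generate_synthetic_dataset()` emulates them from the constitutive model:
25 points per mode by default, amounts of shear up to 0.5 and stretches up
to 1.2 (the ranges spanned by the reported tests), plus optional Gaussian
noise.  The generator reproduces the *shape* of such data (monotone grids,
exponential stiffening, shear linearity) but not inter-specimen
variability, heteroscedastic measurement error, or softening near rupture —
so a perfect noiseless recovery demonstrates correctness of the estimator,
not robustness to real experimental artefacts.  With 1 kPa noise the
Monte-Carlo bias of all four parameters stays below 5%.

## The two benchmark studies

**Notched-plate anisotropy sweep** (`run_senp_sweep()`).  A 1 mm × 1 mm
plane-strain plate with a mid-height edge slit to its centre, a single fibre
family at 45°, and the sensitivity-study constants $\mu = k_1 = k_2 = 1$,
$\kappa = 3$ kPa, $g_c^{\mathrm{iso}}/l = g_c^{\mathrm{ani}}/l = 10^{-2}$ kPa,
$l = 0.1$ mm.  The bulk failure surface is reached at roughly 9% remote
strain, so the run control matters: the default 160 increments to
$u_{\max} = 0.2$ mm let the staggered crack outrun the bulk loading, and the
pull stops once the thresholded band ($d \ge 0.8$) reaches an outer
boundary — beyond that point a broken plate only accumulates meaningless
bulk damage.  The crack angle is the principal direction of the thresholded
element centroids beyond the notch tip.  At the default 50×50 mesh the sweep
over $\omega_M \in \{0, 1, 10, 500\}$ yields angles of roughly 3°, 22°, 44°
and 43° (the last two at the saturation plateau, within the degree-scale
angle-extraction resolution) and strictly increasing peak forces — the isotropic mode-I path, a
monotone rotation towards the fibres, saturation at the fibre angle, and the
elevated fracture force under strong anisotropy.

**Tube dissection demonstration** (`run_tube_demo()`).  An idealised
ascending-aorta segment ($R_i = 15$, $R_o = 17.5$, $H = 40$ mm) with four
medial sub-layers (0.375 mm each) and two adventitial sub-layers (0.5 mm),
an initial tear of angle $\beta \in \{30^\circ, 60^\circ\}$ and width 2 mm
carved through the three innermost sub-layers as a meshed traction-free
void, and per-layer constants from `aorta_layer_table()`: the degenerated
*media 3* carries the medial fit with low fracture resistance
($g_c^{\mathrm{iso}}/l = 6$, $g_c^{\mathrm{ani}}/l = 18$ kPa), healthy media
are 20% stiffer, the adventitia stiffer still, and $\omega_M = 10^3$
everywhere with $l = 0.1875$ mm.  Loading is a physiological saw-tooth
cycle (pressure 0→120→80 mmHg, axial displacement ramped to 8 mm — an axial
stretch of 1.2 — then held, twist to 10°) followed by a supra-physiological
one (600 mmHg, 30° twist), with snapshots at instants A ($t=0.4$),
B ($t=1.2$) and C ($t=1.6$).  The reported metric is the volume fraction of
the degenerated layer with $d \ge 0.8$.  At the default desk scale
(`n_theta = 24`, 12 axial cells refined around the tear, ≈8,000 tetrahedra)
the demonstration shows no damage zone at the physiological peak, a damage
zone at instant B that grows with the tear size ($\approx 7\%$ for
$\beta = 60^\circ$ versus none above threshold for $30^\circ$), and a
nodally non-decreasing field through instant C.  The published study runs
the same configuration at roughly $10^5$ elements, where the damage zone
resolves into a visibly helical band; at desk scale only the integral
metrics and their ordering are meaningful, which is what the tests assert.

## Parameter defaults worth knowing

| Parameter | Default | Why |
|---|---|---|
| $\kappa$ | $3\mu$ | The sensitivity study pairs $\mu = 1$ kPa with $\kappa = 3$ kPa; the ratio, not the absolute value, is what generalises to the 100 kPa-scale tube layers. |
| $a_{\mathrm{iso}}, a_{\mathrm{ani}}$ | 2 | Quadratic degradation. |
| $\eta$ | 0 | Rate-independent evolution; $\eta > 0$ is exposed for continuation at large $\omega_M$. |
| `tension_only` | `TRUE` | Compressed fibres store no energy. |
| `resid_stiff` | 1e-6 (1e-3 in the tube demo) | Tangent invertibility for broken elements. |
| `degrade_volumetric` | `TRUE` (`FALSE` in the tube demo) | See below. |

Two stabilisations are specific to the tube demonstration.  First, the
residual stiffness is raised to 1e-3.  Second, the *volumetric* stiffness is
excluded from degradation inside the solver (`degrade_volumetric = FALSE`):
with the quadratic $g(d)$ a fully broken medial element, squeezed between
intact layers under an 80 kPa transmural pressure, otherwise inverts
(non-positive Jacobian) and terminates the run near the middle of the
supra-physiological ramp.  Keeping $\kappa$ undegraded preserves resistance
to volumetric collapse while the deviatoric and fibre stiffness still
vanish; the failure criterion is untouched — it always uses the full
effective $\Psi_0^{\mathrm{iso}}$ including its volumetric part.  The
default for every other computation degrades the full isotropic energy.

## Validation strategy and limitations

The test suite prefers independent oracles over regression values: stress =
finite difference of energy and tangent = finite difference of stress at
random states; invariance of the invariants under 100 random rotations;
the homogeneous phase-field solution $d = \mathcal H/(1+\mathcal H)$ to
1e-10; the $e^{-x/l}$ profile with $O(h^2)$ convergence; a unit regularised
crack surface for the optimal profile by quadrature; a single-element patch
test against the closed-form homogeneous stress; small-pressure inflation
against the thick-walled Lamé solution (within 1%); and finite inflation
against an independent 1-D axisymmetric shooting solution of the radial
equilibrium ODE (displacement within 1%, hoop-stress profile within 3%).
The identification is validated by exact recovery from noiseless synthetic
data and by the Monte-Carlo bias study.

Known limitations: P1/Q1 elements with full integration can lock for
$\kappa/\mu \gg 1$ (the moderate default ratio of 3 avoids this; no
selective reduced integration is implemented); the one-pass split
under-predicts crack speed, so increment counts are part of the study
definitions; the tear is a meshed void, not an enriched discontinuity, and
its faces are never pressurised; no contact between crack faces, so
re-closing cracks can interpenetrate; no viscoelasticity, residual stress,
or growth/remodelling.  Desk-scale meshes reproduce orderings and integral
metrics of the reference studies, not their pointwise fields.
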