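---
title: "Methods: voxelized porous-media modelling of convection-enhanced delivery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelized porous-media modelling of convection-enhanced delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cedsim simulates convection-enhanced delivery (CED) — the direct, pump-driven
infusion of a macromolecular tracer into tissue — in a heterogeneous solid
tumor using an image-based ("voxelized") porous-media model: every imaging
voxel is a computational cell carrying its own vascular leakiness and
porosity, estimated voxelwise from dynamic contrast-enhanced (DCE) MRI
concentration curves.  This vignette explains the model, the numerical
choices, the synthetic phantom that stands in for undeposited animal data,
and what the package's tests do and do not establish.

## The model

**Tracer-kinetic stage.**  Each voxel's contrast-agent concentration
$C_t(t)$ is described by a two-compartment (Tofts) exchange model

$$\frac{dC_t}{dt} = K^{trans} C_p(t) - \frac{K^{trans}}{\phi} C_t,
  \qquad C_t(0)=0,$$

with $C_p(t)$ the arterial input function (AIF), $K^{trans}$ the
plasma-to-interstitium rate-transfer constant (min$^{-1}$; a vascular
leakiness measure) and $\phi$ the extracellular-extravascular volume
fraction, which the porous-media stage reads as porosity.  For the
biexponential AIF $C_p = \sum_k A_k e^{-m_k t}$ the solution is the closed
form $C_t = K^{trans}\sum_k A_k\,(e^{-m_k t}-e^{-k_{ep}t})/(k_{ep}-m_k)$,
$k_{ep}=K^{trans}/\phi$, evaluated in a cancellation-safe form so the
$k_{ep}\to m_k$ limit is exact.  `fit_dce_voxel()` inverts it by bounded
Levenberg–Marquardt least squares from three fixed starting points
($K^{trans},\phi$) = (0.01, 0.1), (0.1, 0.3), (1.0, 0.6) in min$^{-1}$/–,
ties broken by residual then by smaller $K^{trans}$, so results are
deterministic.  The slow alternative — integrating the ODE numerically per
evaluation — is retained in the test suite as the independent oracle.

**Steady interstitial flow.**  The interstitium is a rigid porous medium.
Continuity with distributed fluid exchange and the single-voxel CED source
reads

$$\nabla\cdot v \;=\; \Phi_v\,\hat K^{trans} \;-\;
  L_{p,ly}\frac{S_L}{V}\,(p - p_L) \;+\; \frac{Q}{V_{vox}}\,\delta_{site},
  \qquad v = -K\,\nabla p,$$

where Starling's law gives the filtration rate
$\Phi_v = L_p\frac{S}{V}\bigl(p_v - p - \sigma(\pi_v-\pi_i)\bigr)$, scaled
by the normalized leakiness map $\hat K^{trans}$ (voxel $K^{trans}$ over
its tissue-wise average) so leaky rim voxels filter proportionally more.
Lymphatic drainage acts in host tissue only — tumors lack functional
lymphatics.  Filtration vanishes at the effective pressure
$p_{eff} = p_v - \sigma(\pi_v - \pi_i)$ (2759.2 Pa for tumor defaults),
the plateau to which a sealed tumor equilibrates.  Hydraulic conductivity
follows the porosity power law $K = M_t\,\phi^\gamma$ with $M_t$ fixed per
tissue by $K(\phi_{0,t}) = K_{0,t}$; $\gamma$ (default 3, the
Carman–Kozeny-like exponent) sets how strongly conductivity tracks local
porosity and is the knob of the conductivity sensitivity study
($\gamma \in \{3, 5, 10\}$).  Exterior (air) voxels get a constant
conductivity two orders of magnitude below host, which realises skin
impermeability without internal boundary conditions; measured interface
velocities are below 1% of the interior peak.

**Tracer transport.**  On the frozen steady flow field the normalized
concentration obeys an advection–diffusion equation with
$D_{eff} = D_{free}\,\phi^{n}$ ($n = 1$) and zero diffusivity outside the
animal.  The infusion voxel is held at normalized concentration 1
throughout (pore fluid at infusate concentration, the normalization
$c = c_t/(\phi_{inf} c_{inf})$); the initial condition is zero elsewhere.
Albumin is not passively cleared through capillaries on the one-hour time
scale, but fluid *drainage* pathways — lymphatic uptake, and net capillary
reabsorption wherever CED pressurizes tissue above $p_{eff}$ — must carry
tracer out at the local pore concentration: a sink-free conservative form
on a divergent flow field would concentrate tracer above the infusate
level at reabsorption sites (we measured $c_{max} = 1.56$ without the
term), which is unphysical for a sieved macromolecule and would break the
maximum principle.  With the drainage term the transport operator is an
M-matrix and $0 \le c \le 1$ holds exactly.

## Discretization and solvers

Both PDEs use cell-centred finite volumes on the voxel grid.  Face
conductances are harmonic means of the adjacent cell coefficients times
face area over centre distance — the standard choice for discontinuous
coefficients (tumor/host/exterior jumps), preserving flux continuity.
Zero-pressure Dirichlet conditions at the cut ends of the imaged volume
(the two box faces transverse to the limb axis, configurable metadata) are
imposed through ghost half-cell conductances, keeping the system symmetric
positive definite; all other outer faces are walls.  The affine
pressure-dependence of the Starling and lymphatic terms goes on the
diagonal, so the steady pressure is one exact linear solve — no nonlinear
iteration.  Small or plate-like systems use CHOLMOD's sparse Cholesky;
large near-cubic blocks (where 3-D fill-in is prohibitive) use
Jacobi-preconditioned conjugate gradients to a relative residual of
$10^{-9}$; both paths are deterministic and residual-checked against the
$10^{-8}$ tolerance.

Transport uses first-order upwind advection on the face Darcy fluxes and
harmonic-mean face diffusivity, integrated by backward Euler on advection
and diffusion together.  An explicit advection step was rejected: the CED
source concentrates the flow in one voxel, giving local CFL limits of
0.05–0.3 s at 3 µL/min and ~40k substeps per simulated hour.  Implicit
upwind is equally monotone and unconditionally stable, and the system
matrix is factorized once (sparse LU) and reused across all time steps;
the default step is 5 s (1 s changes the reported distribution volumes by
less than a voxel).  Outflow at cut-end faces is advective with zero
diffusive flux; inflow carries zero concentration.  A per-step discrete
mass audit checks that the change in total tracer $\sum \phi V c$ equals
influx from the held voxel minus boundary and drainage outflux; it closes
to machine precision by construction, so the audit guards regressions
rather than tuning.

Verification uses two closed forms.  A homogeneous spherical tumor with
Starling filtration, no lymphatics and $p=0$ at the rim has
$p(r) = p_{eff}\bigl[1 - (R/r)\sinh(\alpha r/R)/\sinh\alpha\bigr]$,
$\alpha = R\sqrt{L_p (S/V)/K}$ — elevated, near-uniform core pressure
dropping steeply at the periphery.  The FV solution on a $64^3$ embedding
matches it to 0.04% relative $L_2$; the embedded rim uses Shortley–Weller
fractional face distances computed from the exact sphere crossing (linear
level-set interpolation is only first order on curved boundaries and
would mask the scheme's second-order convergence, visible as the ~4×
error drop from $32^3$ to $64^3$).  A CED-only solve against the Darcy
point source $p = Q/(4\pi K r)$ (analytic values imposed on a distant
spherical shell so the comparison is not polluted by the finite domain)
agrees within 5% on a 5–15 voxel annulus.

## The synthetic phantom

The animal DCE-MRI maps behind the original study are not deposited, so
`make_phantom()` generates the study conditions: a 20 × 10 × 9 mm³ box at
MRI resolution (0.104 × 0.104 × 1 mm; `default_grid(2)` halves the
in-plane resolution for routine work), an elliptic-cylinder "leg" along x
with exterior margin, cut ends at the x faces, and an ellipsoidal tumor
(semi-axes 2.5 × 1.5 × 1.5 mm) abutting the skin with a 0.3 mm host gap.
Property fields are Gaussian-correlated (0.5 mm) random fields with
tissue-wise means matched exactly by affine rescale: $K^{trans}$ 0.1
(tumor) / 0.01 (host) min$^{-1}$ with CV 0.3 and a 3× perfused-rim
enhancement; porosity 0.40 / 0.20 with CV 0.15 and a 1.3× elevation in
the tumor core.  The core elevation encodes the necrotic, cell-poor
centre typical of fast-growing murine sarcomas (extracellular fraction
rises where cells die), complementary to the rim-enhanced leakiness, and
porosity is smoother than leakiness, as DCE-derived $v_e$ maps are.  This
structure matters mechanically: with conductivity $\propto
(\phi/\phi_0)^\gamma$, the $\gamma$ sensitivity study's direction —
lower peak tumor pressure and smaller distribution volume at higher
$\gamma$ — requires the infusion region not to sit in a low-porosity
pocket, otherwise the local conductivity collapse under large $\gamma$
inflates the pressure spike at the catheter instead.  The means, CVs and
factors are literature-typical placeholders (the source study does not
print its averages) and are all spec fields.  The phantom is seeded and
bit-reproducible.  It does not emulate MR signal physics, T1 mapping,
partial-volume or motion artefacts, vessel-scale anatomy, or anisotropic
fibre structure — passing tests show the *solvers and estimators* behave
correctly under realistic heterogeneity, not that any specific animal's
maps are reproduced.

Forward DCE curves for fitting tests come from the same closed form used
by the estimator *plus* an independent stiff-ODE oracle in the tests, so
inverse-crime recovery (noise-free error < 0.1%) and Monte-Carlo recovery
under 5% Gaussian noise (median $K^{trans}$ error < 10% over 200 voxels)
are both exercised.  The default AIF is a population-style biexponential
(amplitudes 3.0/0.7 mM, decays 0.25/0.015 min$^{-1}$) — the study's own
AIF is not printed; fitting tests are self-consistent by construction.

## The parameter study

`run_parameter_study()` varies one factor at a time around the baseline
(centre-of-tumor catheter, 0.3 µL/min, $\gamma = 3$): flow rates 0.3, 1,
3 µL/min; catheter at the tumor centroid, at the tumor–host interface,
and at the anterior tip; $\gamma$ = 3, 5, 10.  All runs share one phantom
seed.  Distribution volume $V_d$ is the tissue volume above 15% of the
maximum concentration (the held infusion voxel, so the threshold is 0.15
during infusion); $V_i = Q\,t$.  Because coverage comparisons across flow
rates are only meaningful at matched infusion volume, each run also
records the time at which it reaches the baseline's final $V_i$ (18 µL).
Whole-leg $V_d(V_i)$ is fit linearly; tumor $V_d(V_i)$ with
$V_{max}(1-e^{-V_i/\tau})$, forced through the origin (zero infusate
occupies zero volume), by bounded multistart least squares.

On the fixed-seed baseline phantom (96 × 48 × 9 grid) the four headline
behaviours of the modelled system reproduce: the distribution is
asymmetric (centre-of-mass offset ≈ 4.5 voxels from the catheter);
whole-leg $V_d$ is linear in $V_i$ ($R^2 > 0.99$) while tumor $V_d$
saturates (exponential beats linear); at matched $V_i$, higher flow rates
cover at least as much of the tumor with a smaller extra-tumoral
fraction; and raising $\gamma$ monotonically lowers peak tumor pressure
and shrinks tumor $V_d$.  The centre catheter yields the best tumor
coverage of the three sites.

## Numerical and design choices, limitations

* Internal units are strictly SI; $K^{trans}$ is converted from
  min$^{-1}$ and flow rates from µL/min at a single entry point.  Voxel
  indices are 1-based array indices in (x, y, z) order.
* The interstitial fluid velocity is reported as the pore velocity
  $v/\phi$ (the standard porous-media convention); both the Darcy flux
  magnitude and the pore speed are exported.
* The infusion voxel acts simultaneously as the continuity-equation
  source $Q/V_{vox}$ and the concentration Dirichlet node, matching the
  described setup.
* Exterior porosity is the sentinel `NA` in maps; solvers substitute an
  effective value of 1 there, with zero diffusivity and sources.
* Cut-end identification is explicit metadata, never inferred from
  anatomy; the default (x faces) is the configuration used throughout.
* Problem sizes in the shipped tests: verification oracles at $32^3$ and
  $64^3$; the conservation audit at full imaging resolution
  (192 × 96 × 9 ≈ 166k voxels, 1 h of infusion at 10 s steps); the
  parameter study at 96 × 48 × 9 with 5 s steps.
* Not modelled: cannula geometry and backflow along the needle, tissue
  deformation/poroelastic swelling, transcapillary albumin exchange,
  binding or metabolism, anisotropic conductivity, vessel networks.
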