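---
title: "Methods: coupled electromagnetic-thermal simulation of multi-position microwave ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled electromagnetic-thermal simulation of multi-position microwave ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Microwave ablation (MWA) destroys liver tumors by depositing 2.45 GHz
electromagnetic energy through an interstitial single-slot coaxial antenna.
For large tumors (diameter > 3 cm) a single ablation either under-treats the
tumor or, at higher power and duration, destroys too much healthy tissue.
`ablatesim` simulates the *multi-ablation* alternative: one antenna visits
several intratumoral positions sequentially, and the package accounts for
the resulting ablation volume, healthy-tissue damage and residual tumor.

The simulation couples four models, one-way, on a shared tetrahedral mesh:

1. **Wave propagation.** The time-harmonic curl-curl equation
   $\nabla\times\mu_r^{-1}(\nabla\times \vec E) - k_0^2\,\varepsilon_R \vec E = 0$
   with complex relative permittivity
   $\varepsilon_R$, a perfect-electric-conductor (PEC) condition
   $\hat n\times\vec E=0$ on the antenna metal, a first-order absorbing
   port condition carrying the incident coax field, and a first-order
   absorbing condition on the exterior. Discretized with lowest-order
   Nédélec (edge) elements, whose degrees of freedom are tangential field
   components on mesh edges, so only tangential continuity is enforced —
   the property that makes them free of the spurious modes nodal
   discretizations of Maxwell suffer from.
2. **Heat source.** $Q_e = \tfrac12\sigma|\vec E|^2$ (W/m³) and
   $\mathrm{SAR} = Q_e/\rho$ (W/kg), element-wise.
3. **Pennes bioheat.**
   $\rho C\,\partial T/\partial t = \nabla\cdot(k\nabla T) + Q_e +
   \rho_b\omega_b C_b (T_b - T) + Q_m$ with temperature-dependent effective
   specific heat (water vaporization), affine $k(T)$, an irreversible
   perfusion shutdown at 60 °C, and an insulated exterior. Nodal P1 finite
   elements, lumped mass, backward Euler.
4. **Cell death and contraction.** The three-state alive/vulnerable/dead
   kinetic model integrated per node against the temperature history, and a
   temperature-banded weighted dose (TTI) driving a power-law localized
   contraction estimate at probe points.

# Conventions and the electromagnetic weak form

We use the engineering time convention $e^{+j\omega t}$, under which the
lossy permittivity is
$\varepsilon_R = \varepsilon_r - j\sigma/(\omega\varepsilon_0)$ and *all*
absorption mechanisms (volume conduction loss, port, exterior absorber)
enter the complex bilinear form with the same positive imaginary sign,
making the discrete operator provably dissipative
($\mathrm{Im}\,x^H A_c x \ge 0$) — a property the test suite asserts on
random vectors. Integrating the curl-curl term by parts gives the boundary
term $+\oint[\hat n\times(\nabla\times\vec E)]\cdot\vec W\,dS$ (a sign
worth double-checking numerically: we pin it in a test against a
polynomial field), into which the port and absorbing conditions are
substituted. The complex system $A_c x = b_c$ with $A_c = A_{re} + jA_{im}$,

$$A_{im} = k_0^2\frac{\sigma}{\omega\varepsilon_0}M
  + \beta M_{S_p} + k_0 M_{S_l},\qquad
  b_c = +2j\beta \oint_{S_p}\vec E_{inc}\cdot\vec W\,dS,$$

is solved as the equivalent real $2N\times 2N$ block system
$\left[\begin{smallmatrix}A_{re}&-A_{im}\\A_{im}&A_{re}\end{smallmatrix}\right]
\left[\begin{smallmatrix}E_{re}\\E_{im}\end{smallmatrix}\right]=
\left[\begin{smallmatrix}b_{re}\\b_{im}\end{smallmatrix}\right]$,
whose two block rows are precisely the real-valued weak-equation pair of
the wave model. For the factorization we use the algebraically identical
*symmetric indefinite* arrangement
$\left[\begin{smallmatrix}A_{re}&-A_{im}\\-A_{im}&-A_{re}\end{smallmatrix}\right]$
(right-hand side $[b_{re}; -b_{im}]$), which CHOLMOD's sparse LDLᵀ factors
an order of magnitude faster than a general sparse LU; a native dense
complex solve is retained as a cross-check oracle and the block/complex
equivalence is asserted to 1e-10 in the tests. Residuals are checked
against 1e-8 after every solve.

Element matrices use exact closed-form barycentric integration (for
lowest-order edge elements every volume integrand is a quadratic
polynomial, so this equals any quadrature rule of degree ≥ 2); surface
terms use a degree-4 triangle rule. The independent test oracle integrates
the same matrices with a subdivided quadrature on a separate code path.
Vacuum permittivity is kept at $8.8\times10^{-12}$ F/m, the value the
electromagnetic model is parameterized with; $c$, $\eta_0$, $k_0$ and
$\beta$ are derived from it for internal consistency.

# Geometry, phantom mesh and the numerical antenna

The liver is a cylinder (radius 4 cm, height 8 cm), the tumor a concentric
sphere of radius 2 cm (volume 33.5 cm³). The phantom mesh is a structured
graded tensor grid: 1-D axes cluster geometrically around every scheduled
antenna axis (and around the tip/slot band vertically), an elliptical
square-to-disk map places lateral boundary vertices exactly on the
cylinder, and each hexahedral cell splits into six tetrahedra (Kuhn
subdivision, conforming). One `scale` knob multiplies all target cell
sizes, so the same geometry runs from desk-scale tests to finer studies.
Because the grid clusters at *every* scheduled position, one mesh serves
the whole protocol: moving the antenna only re-tags cells and surfaces, so
temperature and cell-state fields carry over with no interpolation error
and the old antenna track reverts to tissue. (A general barycentric
`transfer_fields()` remains available — and tested — for workflows with
per-position meshes.)

The antenna cross-section (inner conductor 0.135 mm, dielectric 0.47 mm,
catheter 0.895 mm) is far below any affordable cell size, so the phantom
builds a *numerical antenna* with the same topology: a dielectric core of
effective radius $\max(r_{diel}, 1.3h)$ around the axis, a PEC sheet of
interior facets at the core/catheter interface (the outer conductor) that
opens over a ring at slot height, a catheter annulus outside it, and — the
one component that cannot be a volume at this resolution — the inner
conductor as a *PEC wire* of constrained edges along the antenna axis,
which the grid places exactly on a grid line. The wire matters: without
it the core is a hollow guide far below cutoff at 2.45 GHz and transports
essentially no power to the slot. The slot ring keeps its physical 1 mm
height whenever the vertical grid resolves it and otherwise inflates to
about one cell.

The antenna enters through the bottom face of the cylinder so its shaft
crosses the tumor and the tip sits at the scheduled position: the heated
oval of a single-slot antenna develops around the slot and back along the
feed side of the shaft, so a tip placed a little past the tumor centre
lets that oval cover the tumor chord. (With the opposite orientation —
shaft exiting on the far side — the tumor hemisphere behind the tip can
never be heated in a few minutes, and near-complete kills of a 4 cm tumor
would be geometrically impossible.) The slot's axial placement is not part
of the treatment tables; the default puts its near edge 2.5 mm from the
shorted tip on the feed side, in the range of single-slot designs. It is a
configuration parameter (`slot_offset`), as are all antenna radii.

The port excitation is the coaxial TEM profile $E(r) = C/r$ with $C$
chosen so the Poynting flux equals the requested input power
($\eta = \eta_0/\sqrt{\varepsilon_r}$, $\beta = k_0\sqrt{\varepsilon_r}$);
the generic plane-wave incident form remains available. On coarse meshes
the crude discrete transmission line is imperfectly matched, so part of
the nominal input reflects; by default `run_protocol()` rescales the
(linear) solution so that the power *absorbed in tissue* equals the
protocol's input power — the way clinical generators regulate delivered
power — keeping the thermal problem comparable across resolutions
(`normalize_power = FALSE` disables this).

# Thermal model details

The effective specific heat is $C(T) = C_t - \alpha\,dW/dT$ with $W(T)$
the tissue water mass fraction: a plateau near 0.778 decaying
exponentially toward 103 °C, a steep cubic vaporization transition on
(103, 104] °C, and a slow exponential tail above. The transition cubic is
the Hermite join of the two exponential branches (continuous in value and
slope); its leading term is $0.0289\,T^3$ in absolute temperature. The
latent coefficient $\alpha$ is not fixed by the treatment tables; the
default is the water vaporization enthalpy $2.26\times10^6$ J/kg applied
to the mass fraction, with the alternative water-density grouping
available behind `alpha_grouping`. $\Delta k$ of the affine conductivity
defaults to 0 (constant $k$) with an override. The perfusion latch applies
per element at its mean nodal temperature and never resets. Antenna
regions get PTFE-like thermal properties and carry neither metabolic heat
nor perfusion.

Time stepping is backward Euler with single-lag (Picard) evaluation of
$C(T)$, $k(T)$ and the latch at the previous step, dt defaulting to 1 s;
the temperature solve is a sparse Cholesky whose symbolic factorization is
reused across steps. With lumped mass the discrete insulated-domain energy
balance closes exactly per step, which the test suite asserts.

# Cell death, ablation accounting, contraction

The three-state model
$dA/dt = -k_f A + k_b(1-A-D)$, $dD/dt = k_f(1-A-D)$,
$k_f = k_{f0}e^{T/T_k}(1-A)$ is integrated per node with Heun's explicit
scheme, sub-stepped so $\Delta t(k_f+k_b)\le 0.1$; trajectories match an
adaptive ODE oracle to 1e-4 over a (temperature, duration) grid in the
tests, and $A+V+D=1$ holds by construction. The rate constants are not
printed with the treatment tables; defaults follow the established
three-state hyperthermia parameterization
($k_{f0}=3.33\times10^{-3}$ s⁻¹, $k_b=7.77\times10^{-3}$ s⁻¹,
$T_k=40.5$ °C, $A_0=0.99$) and are configuration-exposed. The forward
rate saturates above `T_cap` (150 °C): with constant dielectric
properties the source can push near-antenna nodes to several hundred
degrees, where the extrapolated exponential would only force
astronomically small sub-steps without changing the outcome.

An element is *ablated* when its mean nodal $D+V = 1-A$ reaches the
classification threshold (default 0.8; the acceptance script reports the
0.5/0.8/0.99 sensitivity, since the classification level is itself a
modelling choice). Ablation volume sums ablated tissue elements; healthy
damage is its liver part; remaining tumor is tumor volume minus its tumor
part.

The weighted temperature-time integral applies the band weight of the
*instantaneous* temperature inside the integrand (0 below 12 °C, 0.1573 to
44.1 °C, 0.3011 to 102.1 °C, 0.5416 above) to the positive excess over the
initial temperature, accumulated trapezoidally; a whole-history single
weight would make the dose discontinuous in its inputs. Localized
contraction is $LC = 0.003\,\mathrm{TTI}^{0.4684}$. Probes sit 3 mm and
5 mm radially from the slot of each scheduled position, and each probe's
dose is integrated over its own heating interval; the baseline $T_0$ is
the global initial temperature (37 °C) and does not reset when the
antenna moves.

# The protocol scheduler

A protocol is an ordered set of tip positions with contiguous heating
intervals, half-open on the left ($t_1$ belongs to position 1's
interval). Pairwise spacing must respect a 14 mm minimum — the separation
that avoids unablated gaps without clefting. Four presets reproduce the
studied treatments: the square pattern $(\pm7, \pm7, 10)$ mm at 3 or 4
minutes per position, an equilateral 14 mm triangle at 5 minutes per
position, and a single central 20-minute ablation, all at 50 W / 2.45 GHz.
Within an interval the source is frozen (the dielectric properties are
temperature-independent constants, so the electromagnetic problem is
solved once per position); temperature, cell state and probe histories are
continuous across switches.

# Problem sizes and verification scope

The default desk-scale configuration used by the acceptance script runs
the multi-position phantoms at `scale = 2.6` and the single-position
phantom at `scale = 1.7` — chosen so every protocol is simulated at a
comparable cell count (~13–17k tetrahedra; the graded grid clusters at
every scheduled axis, so a single-cluster phantom at the same knob would
be much coarser) — with dt = 4 s; EM solves take ~30 s each on one core.
The test suite uses smaller fixtures (cubes of 48–1296 cells, phantoms at
scale 4–6, and protocol runs at scale 3.4/2.2). At these
resolutions the numerical antenna is several times fatter than the
physical one and the port mode is crude, so absolute near-field values
carry O(1) discretization effects that the power normalization only
partially compensates; the quantities that are robust at desk scale are
the closed-form operations (doses, rates, accounting), the conservation
and convergence properties, and the *orderings* between protocols. The
synthetic phantom emulates the idealized cylinder/sphere geometry with
homogeneous region properties; it does not emulate vascular heat sinks,
tissue heterogeneity, hydration-dependent dielectric collapse, or
mechanical deformation, so passing tests validate the numerical method
and the model couplings, not clinical prediction.

Known limitations: first-order absorbing boundaries (no PML); no antenna
impedance/S11 accounting; constant dielectric properties (temperatures
near the slot overshoot physically because desiccation is not fed back);
the three-state constants and the latent-heat coefficient are
literature defaults, not fitted values; and full-resolution replication of
the reference ablation-volume table is a cluster-scale computation, out of
scope for the desk configuration.
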