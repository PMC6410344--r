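---
title: "Modeling gold-nanoparticle hyperthermia: from plasmon resonance to tumor regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gold-nanoparticle hyperthermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(nanotherm)
library(ggplot2)
```

nanotherm simulates photothermal cancer therapy with gold nanoparticles as a
chain of four physical models: plasmonic light absorption by the particles,
heat generation and transport in perfused tissue, thermally induced cell
death, and tumor growth across a multi-session treatment course. This
vignette explains each model, its assumptions and tunable parameters, the
numerical choices behind the solvers, and the design decisions taken where
the problem was genuinely open.

## Optical constants and the surface scattering correction

All optics start from wavelength-tabulated complex refractive indices
(`optical_material()`), shipped as plain CSV fixtures over 400–1100 nm:

* **gold** — the Brendel–Bormann analytic dispersion model with the
  parameters of Rakić et al. (1998), evaluated onto a 1 nm grid. Gold
  tabulations differ measurably in the interband region (Johnson–Christy
  and the Rakić Lorentz–Drude variant place the 40 nm sphere resonance
  about 7 nm bluer); the Brendel–Bormann model is the standard
  "Rakić" entry in optical-constant databases and is used throughout.
* **silica** — the Malitson (1965) Sellmeier dispersion, lossless.
* **water** — constant n = 1.33, the usual visible-range value.
* **TiO₂** — constant n = 2.5 (a representative visible-range value for
  titania overlayers).

Tables store the engineering-convention pair (n, k); every dielectric
function returned by the package uses the physics convention
ε = ε₁ + iε₂ with ε₂ ≥ 0 for absorbing media. The conversion happens in
exactly one place (`bulk_dielectric()`, ε = (n + ik)²) to avoid
double-negation mistakes. Interpolation is linear in n and k separately,
never in ε, which keeps lossless materials exactly lossless.

Structures thinner than the ~42 nm electron mean free path of gold scatter
conduction electrons at their surfaces. `size_corrected_dielectric()`
removes the bulk Drude damping and restores it with the reduced mean free
path L_eff:

ε(ω, L_eff) = ε_bulk(ω) + ωp²/(ω² + iω v_F/L∞) − ωp²/(ω² + iω(v_F/L∞ + A v_F/L_eff))

with ωp = 1.37×10¹⁶ rad/s, v_F = 1.4×10⁶ m/s, L∞ = 4.2×10⁻⁸ m and A = 1
(`drude_constants()`). L_eff defaults to the gold layer thickness for
shells and to the radius for solid spheres. As L_eff → ∞ the two terms
cancel exactly — a property the test suite asserts.

## Mie theory for spheres and nanoshells

`qabs_sphere()` and `qabs_shell()` evaluate the partial-wave absorption
efficiency

Q_abs = (2/x₂²) Σₙ (2n+1) (Re[aₙ+bₙ] − |aₙ|² − |bₙ|²),

with the coated-sphere coefficients aₙ, bₙ and layer auxiliaries Aₙ, Bₙ;
a solid sphere is the Aₙ = Bₙ = 0 case. Numerical choices:

* Series truncation at the Wiscombe order nmax = ⌈x + 4x^{1/3} + 2⌉; the
  tests verify that five further orders change Q_abs by < 10⁻⁸ for x ≤ 20.
* Riccati–Bessel ψₙ at complex argument by downward recurrence
  (normalised against ψ₀ = sin z), χₙ by upward recurrence — the stable
  direction for each solution family; ξₙ = ψₙ − iχₙ.
* The correctness anchor is a frozen set of reference efficiencies from an
  independent logarithmic-derivative (BHMIE-style) implementation, matched
  to 10⁻⁶ relative, plus closed-form limits: the Rayleigh dipole formula
  for d ≤ 2 nm, degenerate shells against solid spheres, and the
  vanishing-core limit.

With these ingredients the 40 nm gold sphere in water peaks at 532 nm and
the 30 nm silica-core/gold-shell particle at 593 nm (both computed by
`scripts/acceptance.R`); thinner shells shift further red, the classic
nanoshell tuning handle.

```{r spectra}
grid <- seq(450, 800, by = 2)
sp_sphere <- absorption_spectrum(sphere_spec(40), grid)
sp_shell  <- absorption_spectrum(shell_spec(10, 15), grid)
glance(sp_sphere)
glance(sp_shell)
autoplot(sp_shell)
```

## Gans theory for prolate ellipsoids

For particles elongated into prolate spheroids (semiaxes a ≥ b = c),
`gans_absorption()` evaluates the quasi-static cross section with
depolarization factors P_A (long axis) and P_B = P_C = (1 − P_A)/2
(`depolarization_factors()`). At axis ratio 1 the expression reduces
algebraically to Rayleigh sphere absorption — asserted to 10⁻⁶ — and with
growing ratio the long-axis resonance red-shifts monotonically. No
retardation correction is applied, so results are size-accurate only for
particles much smaller than the wavelength; the model is included for the
shape-tuning story, not for quantitative large-particle work.

## The size-scaling exponent

`sphere_size_scan()` computes σ_abs(532 nm) for 25 log-spaced diameters
between 10 and 1000 nm and `fit_power_law()` fits σ = α d^p. The fit is
performed by nonlinear least squares **on the linear scale** (the
convention of a `y = a·x^b` curve fit to raw cross sections, where the
largest particles dominate), giving p ≈ 1.45. An ordinary log-log
regression, available as `scale = "log"`, weights all decades equally and
gives a distinctly larger exponent (≈ 1.9–2.0, the small-particle d³
regime blending into the geometric d² regime); the linear-scale exponent
is the one comparable to reported size-scaling fits of this kind. Both
estimators recover noiseless synthetic power laws to machine precision.

## Nanoparticle transport and the Pennes bioheat equation

The thermal stage works on a 1-D radially symmetric spherical domain
(`radial_grid()`): a tumor of radius 3 mm (volume 113 mm³) embedded in a
healthy-tissue surround out to 9 mm by default. A radial geometry
resolves the dominant gradient of a centrally injected bolus heating a
spherical tumor at a fraction of the cost of a full 2-D/3-D finite-element
model; it cannot represent antenna-shaped microwave fields, for which the
solver instead accepts any user-supplied volumetric source Q(r).

`solve_np_diffusion()` evolves the injected particle concentration with
diffusivity 6.2×10⁻¹¹ m²/s (the tabulated tissue value, configurable),
zero flux at the centre and an absorbing far boundary. The injection is a
central Gaussian bolus (`gaussian_bolus()`, σ = 0.5 mm by default) whose
total particle count matches a 40 µg/mL mass concentration over the tumor
volume via `np_number_density()` (gold 19300 kg/m³, silica 2200 kg/m³).
The optional generation term R_gen (1/m³/s) defaults to zero.

`solve_pennes()` then integrates

ρC_p ∂T/∂t = ∇·(k∇T) + Q + ρ_b C_{p,b} ω_b (T_b − T) + q_met

with per-tissue parameters from `tissue_properties()` (blood, dermis,
epidermis, fat, tumor/muscle). Two unit interpretations were fixed here:
the perfusion column (m³ blood per m³ tissue per second) multiplies
ρ_b C_{p,b} as a volumetric sink rate, and the metabolic heat column is
used directly as W/m³ — its magnitudes (464–1200) are only physical as
volumetric rates; treated as W/kg they would put resting tissue more than
a hundred degrees above arterial blood.

Numerics: finite volumes on the uniform radial grid (face conductances by
harmonic mean, exact symmetry at r = 0), implicit Euler with a fixed
Δt = 0.1 s and the constant system matrix LU-factorised once. The scheme
is unconditionally stable and monotone; equilibrium (no sources, T ≡ T_b)
is preserved to linear-solver roundoff (< 10⁻⁶ °C), a uniform source
against an insulated boundary reproduces the algebraic
source–perfusion balance, and halving the grid spacing moves the centre
temperature by < 0.5%. Laser heating couples in as Q(r) = c(r)·σ_abs·I
(`np_heat_source()`) with σ_abs taken at the spectrum peak and
I = 20 W/cm²; beam attenuation through tissue is neglected, so deposited
power — and hence temperature — is an upper bound. First-crossing times
of the 42/47/50 °C damage thresholds are reported per radius.

## Three-state hyperthermic cell death

Cells move between alive (A), vulnerable (V) and dead (D) states with
A + V + D = 1. During heating (fast, necrotic phase, rates per minute):

dA/dt = −k_f A + k_b (1 − A − D),  dD/dt = k_f (1 − A − D),
k_f = k̄_f e^{T/T_k} (1 − A)

and after treatment (slow, apoptotic phase, rates per hour, k_f = k_b = 0):

dD/dt = k_s (1 − D),  k_s = k̄_s D (1 − D)(D − D_τ)².

T is in °C (T_k is tabulated in °C). V is recovered algebraically from the
conservation law rather than integrated, so A + V + D = 1 holds exactly.
Because A = 1 is a fixed point of the self-catalytic forward rate, the
default initial state seeds a small vulnerable fraction
(A₀ = 1 − 10⁻³, configurable and recorded in the trajectory attributes).
Integration uses lsoda at rtol 10⁻¹⁰/atol 10⁻¹²; frozen reference
trajectories from an independent implicit Runge–Kutta integration at
rtol 10⁻¹² anchor the tests. Shipped parameter sets: melanoma (calibrated
at 48 °C) and prostate (50 °C); the prostate slow-phase entries were
published without supporting data and are flagged
`provenance = "unverified"`.

```{r death}
autoplot(fast_death(death_model_params("melanoma"), 48, 30))
```

### Parameter estimation

`fit_death_params()` fits the model to viability data by bound-constrained
least squares: Levenberg–Marquardt on the residuals with rates on the log
scale, 20 multistarts drawn within the bounds (rates log-uniformly, and
from a moderate 0.02–2 window — at extreme rates the predicted survival
curve is flat and every local method stalls on the zero-gradient plateau).
Fast-mode fits target A(t), slow-mode fits 1 − D(t), matching the
viability semantics of survival assays.

One structural fact matters: at a single heating temperature the data
constrain only the effective rate b = k̄_f e^{T/T_k}, so k̄_f and T_k are
not separately identifiable. Single-temperature fits therefore estimate
(b, k_b) with T_k held fixed (default 40 °C) and report
k̄_f = b e^{−T/T_k}; data spanning several temperatures free all three
parameters. The reproducible quantity is the fitted survival curve, and
the recovery criterion is phrased accordingly: on synthetic data with
noise sd 0.02 the fitted curve lies within 0.05 RMS of the truth in at
least 90% of seeded replicates.

## Tumor growth and the treatment course

Between sessions the tumor grows exponentially, V(t) = V₀e^{a₀t},
evaluated in closed form (`grow()`; no integrator drift). The calibrated
rates are 0.328/day (melanoma), 0.237/day (melanoma under HSP90
inhibition — the inhibitor enters the model only as this reduced regrowth
rate) and 0.243/day (prostate). The tabulated source prints these
magnitudes per second, which would double a tumor in about two seconds;
per-day units are the only reading consistent with the multi-day growth
curves they calibrate, and are used throughout.

`apply_session()` composes one session: fast death at the session
temperature, then slow death over a post-treatment window (48 h default,
truncated to the inter-session gap), then the volume coupling
V_post = V_pre (1 − D_final). Two open choices were fixed:

* **Volume coupling.** Proportional viable volume is the minimal
  assumption linking the (dimensionless) dead fraction to volume;
  `coupling = "alive_fraction"` (V_post = V_pre·A_final) is provided as
  the alternative.
* **Fast→slow hand-off.** The slow phase has no vulnerable state, so the
  vulnerable fraction at the end of heating must be assigned. The default
  (`slow_from = "non_alive"`) counts vulnerable cells as committed to
  apoptosis (D₀ = 1 − A_fast); with the calibrated melanoma parameters
  this gives a per-session kill of ≈ 0.92 and the sawtooth course with
  net shrinkage that the model chain is meant to produce, whereas seeding
  from D_fast alone (≈ 0.26 kill, `slow_from = "dead_only"`) lets
  regrowth dominate every schedule.

Growth is suspended during the slow-death window (the phases are treated
as sequential, matching the damage-then-recovery reading of a 4-day
cycle); a session whose window would overlap the next session is
truncated, or rejected with `truncate_windows = FALSE`. The default
schedules are seven sessions every 4 days at 48 °C/30 min (melanoma) and
days 0, 2, 6 at 50 °C/15 min (prostate), both from V₀ = 113 mm³ (a 3 mm
radius sphere). A session shrinks the course net when its kill fraction
exceeds 1 − e^{−a₀Δt}; the tests construct cases on both sides of that
balance point.

```{r course}
tr <- simulate_course(113.1, melanoma_schedule(),
                      growth_params("melanoma"),
                      death_model_params("melanoma"))
glance(tr)
autoplot(tr)
```

## Synthetic data: what it does and does not emulate

`gen_viability()` and `gen_growth()` generate datasets with the
*statistical structure* of the calibration data the models are meant for:
viability fractions on a time grid at fixed temperature with additive
Gaussian noise clipped to [0, 1] (sd 0.02 default — a typical assay
replicate spread), and volume curves with multiplicative log-normal noise
(sd 0.05 on the log scale; volumes span decades, so errors scale).
Both require an explicit seed and restore the caller's RNG state.

They deliberately do not emulate plate effects, caliper bias,
batch-to-batch heterogeneity or model misspecification. Passing the
round-trip and recovery tests therefore shows the estimation machinery is
correct and well-conditioned under the assumed error model — not that the
three-state model is an adequate description of any particular cell line.

## End-to-end pipeline

`run_np_pipeline()` chains the stages — spectrum → peak σ_abs → injection
and diffusion (1 h) → Pennes heating (10 min) → cell death → treatment
course — from a single validated `pipeline_config()` (YAML-loadable via
`read_pipeline_config()`; a thin command-line wrapper ships in
`inst/cli/`). The heat stage consumes the cross section at the spectrum
stage's peak wavelength, a cross-stage identity the tests assert, and the
run is deterministic given the seed. The cell-death phase runs at the
scheduled constant temperature (48/50 °C) rather than at the
bioheat-computed T(r, t): the spatial temperature field would imply a
spatially resolved kill fraction, which the 0-D death model cannot
represent; the bioheat stage instead answers whether the damage
thresholds are exceeded inside the tumor, which qualitative assertions
cover.

## Problem sizes and runtime

Default analyses are sized for an ordinary single core: spectra at 1 nm
resolution (a few hundred Mie evaluations each), 181-node radial grids
(50 µm spacing) with 0.1 s thermal steps over 10 min of heating, 1 h of
diffusion at 5 s steps, and 50-replicate recovery studies with 5–20
multistarts per fit. All were chosen as the coarsest settings whose
refinement changes the reported quantities by less than the tolerances
the tests assert (grid convergence < 0.5%, series convergence < 10⁻⁸,
kernel agreement < 1%).

## Known limitations

* Quasi-static Gans model without retardation; no nanorod/DDA machinery.
* No Beer–Lambert attenuation of the laser through tissue — peak
  temperatures are upper bounds.
* 1-D radial geometry; no antenna/EM field solver for microwave
  hyperthermia (a generic volumetric source approximates it).
* The prostate slow-death parameters are shipped but unverified.
* Constant-temperature cell death during sessions; no CEM43 thermal-dose
  accounting; no immune-mediated clearance or inhibitor pharmacokinetics.

## References

* Bohren, C. F., Huffman, D. R. (1983) *Absorption and Scattering of
  Light by Small Particles*. Wiley.
* Rakić, A. D., Djurišić, A. B., Elazar, J. M., Majewski, M. L. (1998)
  Optical properties of metallic films for vertical-cavity optoelectronic
  devices. *Applied Optics* 37, 5271–5283.
* Malitson, I. H. (1965) Interspecimen comparison of the refractive index
  of fused silica. *JOSA* 55, 1205–1209.
* Pennes, H. H. (1948) Analysis of tissue and arterial blood temperatures
  in the resting human forearm. *J. Appl. Physiol.* 1, 93–122.
* O'Neill, D. P. et al. (2011) A three-state mathematical model of
  hyperthermic cell death. *Ann. Biomed. Eng.* 39, 570–579.
* Wiscombe, W. J. (1980) Improved Mie scattering algorithms.
  *Applied Optics* 19, 1505–1509.
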