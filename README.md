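# nanotherm

Simulation of gold-nanoparticle photothermal therapy for small solid
tumors, end to end: from the plasmon resonance of the injected particles
to the predicted tumor volume after a multi-session treatment course.
It is aimed at computational-oncology and nanomedicine modelers who want
a tested, scriptable alternative to ad-hoc FEM pipelines for
order-of-magnitude treatment design and for calibrating cell-death and
growth models against viability and caliper data.

## What it computes

**Plasmonic absorption.** Mie partial-wave efficiencies for solid spheres
and concentric core–shell particles,

Q_abs = (2/x₂²) Σₙ (2n+1)(Re[aₙ+bₙ] − |aₙ|² − |bₙ|²),

with the layer auxiliaries Aₙ, Bₙ for shells (Aₙ = Bₙ = 0 for spheres),
a surface-scattering (reduced mean free path) correction to the gold
dielectric for thin layers, Gans theory with depolarization factors
P_A ≤ P_B = P_C for prolate ellipsoids, spectrum scans with peak finding,
and the power-law fit σ_abs ∝ d^p of cross section versus diameter.

**Tissue heating.** Nanoparticle diffusion and the Pennes bioheat
equation on a radially symmetric tumor-plus-surround domain,

ρC_p ∂T/∂t = ∇·(k∇T) + Q + ρ_b C_{p,b} ω_b (T_b − T) + q_met,

with the laser/particle source Q(r) = c(r) σ_abs I and damage-threshold
crossing times at 42/47/50 °C.

**Cell death.** The three-state hyperthermic model (alive A, vulnerable
V, dead D; A+V+D = 1) with fast necrotic kinetics during heating
(k_f = k̄_f e^{T/T_k}(1−A)) and slow apoptotic kinetics afterwards
(dD/dt = k̄_s D(1−D)²(D−D_τ)²), plus bound-constrained multistart
least-squares estimation of its parameters from viability data.

**Treatment course.** Exponential regrowth V(t) = V₀e^{a₀t} between
sessions, composed with per-session kill fractions over a treatment
schedule; an HSP90-inhibition variant enters as a reduced a₀. Synthetic
viability and growth-curve generators make every estimation step testable
without external data.

## Worked example

The 30 nm silica-core/gold-shell particle used for the hyperthermia
scenario, and a seven-session melanoma course:

```r
library(nanotherm)

sp <- absorption_spectrum(shell_spec(10, 15), seq(450, 800, by = 1))
glance(sp)
#>   kind       peak_wavelength_nm peak_value n_wavelengths
#> 1 efficiency                593       2.37           351

tr <- simulate_course(113.1, melanoma_schedule(),
                      growth_params("melanoma"),
                      death_model_params("melanoma"))
head(session_summary(tr), 3)
#>   session   day V_pre_mm3 V_post_mm3 kill_fraction slow_h
#> 1       1     0    113.        9.44          0.917     48
#> 2       2     4     18.2       1.52          0.917     48
#> 3       3     8      2.92      0.244         0.917     48
glance(tr)
#>   V0_mm3 final_volume_mm3 final_day n_sessions mean_kill_fraction
#> 1   113.         0.000315        28          7              0.917
```

The shell resonates at 593 nm with peak efficiency 2.37. Each session
(30 min at 48 °C plus a 48 h apoptotic window) kills 91.7% of the tumor,
more than the 4-day regrowth can replace, so the 113 mm³ tumor shrinks in
a sawtooth to a negligible volume by day 28. `autoplot()` methods draw
each result type; `run_np_pipeline(pipeline_config())` chains spectrum,
diffusion, heating, death and growth from one configuration, and
`inst/cli/nanotherm` exposes the same pipeline as a command-line tool
over a YAML config.

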