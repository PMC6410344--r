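# Frozen reference values computed with independent implementations:
# Mie efficiencies from a logarithmic-derivative (BHMIE-style) algorithm,
# cell-death trajectories from a high-accuracy implicit Runge-Kutta
# integration at rtol 1e-12. Both are algorithmically independent of the
# package's Riccati-Bessel recurrences and lsoda integrations.

# Qabs for solid gold spheres in water (bulk dielectric, no size
# correction): diameter [nm], wavelength [nm], Qabs.
mie_sphere_oracle <- data.frame(
  d = c(5, 12, 25, 40, 60, 90, 150, 250, 400, 800),
  lambda = c(470, 532, 650, 532, 540, 600, 700, 800, 450, 633),
  qabs = c(1.856982198142e-01, 7.947903966628e-01, 6.720979794639e-02,
           2.926281594758e+00, 4.118860712182e+00, 1.634644630895e+00,
           3.429858748039e-01, 1.263368147430e-01, 1.267279736163e+00,
           2.642308108776e-01)
)

# 10 nm silica core / 15 nm outer gold shell in water at 590 nm, shell
# dielectric size-corrected with L_eff = 5 nm.
shell_oracle_590 <- 2.361875135989

# Size-corrected gold dielectric at 532 nm, L_eff = 5 nm (from the shipped
# bulk table).
eps_corrected_532_L5 <- complex(real = -4.1700520220,
                                imaginary = 3.5016794204)

# Three-state model trajectories (calibrated parameter sets):
# melanoma at 48 degC for 30 min from (A, V, D) = (1 - 1e-3, 1e-3, 0)
fast_oracle_melanoma <- c(A = 0.683301185052, D = 0.137767458514)
# prostate at 50 degC for 15 min
fast_oracle_prostate <- c(A = 0.602148540211, D = 0.133741663310)
# melanoma slow phase, D0 = 0.3, 48 h
slow_oracle_melanoma_D03 <- 0.909698975942
# melanoma slow phase seeded from the fast-phase non-alive fraction
# 1 - 0.683301185052, 48 h (session composition)
slow_oracle_melanoma_session <- 0.916551628045

# exact depolarization factors at axis ratio 2
depol_oracle_r2 <- c(PA = 0.173563997534, PB = 0.413218001233)
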