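# fpfa

Fluorescence Polarization and Fluctuation Analysis (FPFA) for R: joint
micro-time / macro-time analysis of polarization-resolved TCSPC photon
streams, plus a Brownian-dynamics photon simulator with full ground truth.

FPFA answers a structural question about protein complexes in solution or in
cells — *how many tagged subunits does a complex have, and are their
fluorophores arranged in close pairs?* — from a single measurement on freely
diffusing complexes. Three observables come out of the same photon records:

- **Time-resolved anisotropy** (photon micro-times, ns): rotational
  diffusion plus, for oligomers, a fast extra depolarization from homo-FRET
  between identical fluorophores within a few nanometres — a proximity gauge.
- **Fluorescence lifetime** (micro-times): a control, since homo-FRET does
  not change it.
- **Diffusion correlation time and molecular brightness** (macro-times,
  µs–s): fluctuation correlation analysis of the parallel × perpendicular
  detector cross-correlation gives the mean occupancy ⟨N⟩ and dwell time
  τ_D of the observation volume; brightness η = ⟨k⟩/⟨N⟩ normalized by a
  monomer reference counts fluorophores per complex.

Core models, in the field's standard notation:

    r(t) = (I∥ − g·I⊥) / (I∥ + 2g·I⊥)          F(t) = I∥ + 2g·I⊥
    G(τ) = (γ/⟨N⟩) · (1 + τ/τ_D)⁻¹ · (1 + (ω/z)²·τ/τ_D)^(−1/2),  γ = 0.35
    η = ⟨k⟩/⟨N⟩        ρ = η_complex/η_monomer   or   ρ = (η − b)/m
    τ_D = ω²/(8D)      V = π^(3/2)·ω²·z/8        E_obs = E·(1 − p)

The last line is the binomial pairing model for hetero-FRET: with donor
fraction p and random 1:1 subunit pairing, the observed per-cell FRET
efficiency is linear in p with intercept and −slope both equal to the
pairwise efficiency E.

## Worked example

Simulate a Venus-dimer-like species (3.1 ns lifetime, 16.4 ns rotational
time, 1 ns homo-FRET exchange, D = 30 µm²/s) in a calibrated two-photon
volume, then run the full analysis:

```r
library(fpfa)

venus2 <- species_spec(mean_N = 2, n_fluor = 2,
                       peak_brightness_per_fluor = 22000,
                       D_um2_s = 30, lifetime_ns = 3.1,
                       theta_rot_ns = 16.4, phi_fret_ns = 1)
cfg <- simulation_config(venus2, omega_nm = 424, z0_nm = 424 / 0.15,
                         duration_s = 2, seed = 11)
sim <- simulate_stream(cfg)

report <- fpfa_analyze(sim$stream,
                       calibration = list(g = 1, omega_nm = 424,
                                          omega_z_ratio = 0.15),
                       eta_reference = 22000)
print(report)
#> <fpfa_report>
#>   in-memory stream: 171554 photons, 2 s, 85777 cps
#>   anisotropy: 1 component(s), tau = 2.44 ns, offset 0.11
#>   lifetime: tau = 3.09 ns
#>   diffusion: <N> = 1.98, tau_D = 0.000714 s
#>   brightness: eta = 4.383e+04 cpsm, rho = 1.99
#>   geometry: V = 0.354 fl, D = 31.5 um2/s, conc = 9.3e-09 M
```

Reading the report: the anisotropy needs a *fast* (2.4 ns) depolarization
component on top of a large residual anisotropy — the homo-FRET signature of
paired fluorophores (a monomer fits a single ~16 ns rotational decay with no
offset); the lifetime is unchanged at 3.1 ns, confirming homo-FRET rather
than quenching; and the normalized brightness ρ = 1.99 counts two
fluorophores per complex. The fitted occupancy ⟨N⟩ = 1.98 (truth 2.0) in the
0.354 fl calibrated volume corresponds to ~9 nM, and τ_D = 714 µs (truth
749 µs) gives D = 31.5 µm²/s via τ_D = ω²/(8D) (truth 30).

The same functions run from a shell through the thin CLI:

```sh
Rscript inst/cli/fpfa simulate -c sim.yaml --seed 7 -o run1.pstr
Rscript inst/cli/fpfa analyze run1.pstr --calib calib.json -o report.json
Rscript inst/cli/fpfa calibrate --mode dilution_series d1.pstr d2.pstr d3.pstr -o calib.json
Rscript inst/cli/fpfa fret points.tsv -o fret.json
```

Photon streams travel in a flat, diffable text format (`# key = value`
header with the instrument metadata, then
`channel  macro_time_ticks  micro_time_ns` rows); see
`?write_photon_stream`.

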