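---
title: "FPFA: models, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FPFA: models, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpfa)
```

Fluorescence Polarization and Fluctuation Analysis (FPFA) reads three
complementary observables out of one polarization-resolved TCSPC
measurement of freely diffusing fluorophore-tagged protein complexes:

* **time-resolved anisotropy** from photon *micro-times* (ns scale), which
  reports rotational diffusion and — through an additional fast decay
  component — homo-FRET between identical fluorophores held within a few
  nanometres of each other;
* **fluorescence lifetime**, also from micro-times, which homo-FRET leaves
  untouched (energy exchange between identical fluorophores shuffles the
  excitation around but does not open a new de-excitation channel);
* **diffusion correlation time and molecular brightness** from photon
  *macro-times* (µs–s scale) via fluctuation correlation analysis, which
  yield the hydrodynamic size and the number of fluorophores per complex.

Together these constrain complex stoichiometry and subunit arrangement far
more tightly than any one FRET readout: brightness counts subunits,
anisotropy tells whether their fluorophores sit in close pairs, and the
correlation time cross-checks the complex's size.

## Micro-time models

With parallel and perpendicular detection channels and a perpendicular
efficiency correction $g$, the anisotropy and total-intensity decays are

$$ r(t) = \frac{I_\parallel(t) - g I_\perp(t)}
               {I_\parallel(t) + 2 g I_\perp(t)}, \qquad
   F(t) = I_\parallel(t) + 2 g I_\perp(t), $$

both on dark-subtracted counts. `time_resolved_anisotropy()` propagates
per-bin Poisson errors by the delta method; bins with no intensity are
flagged `NA` rather than fabricated. The reconstruction
$I_\parallel = F (1 + 2r)/3$, $I_\perp = F (1 - r)/(3g)$ inverts the pair
exactly, which the test suite checks to machine precision.

Decays are fit by weighted least squares to sums of one to three
exponentials (`fit_exponential_decay()`), tail-only: the default window
starts 0.5 ns after the intensity peak, so no instrument-response
deconvolution is attempted (an optional Gaussian timing jitter exists in the
simulator to confirm that sub-100 ps jitter does not move tail fits).
Anisotropy fits include a constant offset (residual anisotropy of slowly
rotating or energy-plateaued species); lifetime fits do not. Model selection
(`select_exponential_model()`) prefers the smaller model unless the reduced
$\chi^2$ improves by more than 20% — a deliberately conservative tie-break so
a fast homo-FRET component is only reported when the residuals demand it.
For a monomeric dye whose anisotropy has fully decayed, setting the
tail-window mean of $r(t)$ to zero gives the g-factor calibration
`calibrate_g_factor()`: $g = \overline{I_\parallel} / \overline{I_\perp}$
over the tail.

A caution from the offset term: for a monomer whose rotational time
($\theta \approx 16$ ns) exceeds the 12.5 ns pulse window, the offset and
$\theta$ are nearly degenerate; fitting a monomer control with
`offset = FALSE` (its anisotropy genuinely decays to zero) removes a several
percent downward bias on $\theta$.

## Macro-time models

`multitau_correlate()` computes the normalized cross-correlation of the two
detectors' count series on a multi-tau grid: lags $1..2m$ at the base width
(default 1 µs), then lags $m{+}1..2m$ at every doubling of the bin width
($m$ = 8 points per octave), for as long as at least $4m$ bins remain in a
segment. Cross-correlating the two polarization channels (rather than
autocorrelating either) removes detector artifacts such as afterpulsing. The
acquisition is split into 10 segments; the reported curve is the segment
mean and its standard error, which also supplies fit weights. The estimator
uses symmetric normalization (each series averaged over the window it
contributes to). A deliberately brute-force twin, `direct_correlate()`,
recomputes the same estimator by per-lag from-scratch binning; the two must
agree to $10^{-10}$ on any stream, which pins down the rebinning
bookkeeping — the part of a multi-tau implementation that usually harbours
bugs. Both implementations share one bin-grid definition (level-$l$ index =
base index integer-divided by $2^l$) because independent floating-point
`floor()` paths can disagree at bin-edge ulps.

The diffusion model fitted to $G(\tau)$ is the single-component two-photon
3-D Gaussian form

$$ G(\tau) = \frac{\gamma}{\langle N\rangle}
   \left(1 + \frac{\tau}{\tau_D}\right)^{-1}
   \left(1 + \left(\frac{\omega}{z}\right)^2
   \frac{\tau}{\tau_D}\right)^{-1/2}, \qquad \gamma = 0.35, $$

with $\gamma$ fixed, never fitted. No triplet/flicker term is included:
fluorescent-protein flickering is not observed under two-photon excitation,
and the analysis assumes diffusion is the only fluctuation source. The fit
adds a free additive baseline by default. This is a numerical-bias control,
not extra physics: any finite-acquisition estimator normalizes by a measured
mean that is itself correlated with the fluctuations, and a simulation box
holding a fixed number of molecules contributes a further $-1/n_{box}$
offset; both are lag-independent to good approximation and otherwise drag
$\tau_D$ down through the heavily-weighted long-lag tail (about 20% in our
experiments). With noiseless model curves the baseline converges to zero and
parameter recovery is exact to six significant figures.

`global_fit_dilution_series()` ties $\omega/z$ and $\tau_D$ across curves
from a dilution series, freeing only $\langle N\rangle$ per curve — the
standard geometry calibration. Replicate handling follows common practice:
`average_correlation_curves()` averages curves before fitting (both routes —
averaging curves or averaging fitted parameters — are available; averaging
curves is the default because it also stabilizes the weights).

## Brightness, geometry and concentration arithmetic

Molecular brightness is $\eta = \langle k\rangle / \langle N\rangle$ (counts
per second per molecule), with $\langle N\rangle$ taken from the $\gamma$-
explicit fit, so $\gamma$ is *not* divided out again. Normalized brightness
$\rho = \eta_{complex}/\eta_{monomer}$ counts fluorophores per complex; in
cells, where autofluorescence offsets the scale, $\rho = (\eta - b)/m$ from
the slope and intercept of a concatemer calibration line
(`fit_brightness_line()`, with 95% confidence and prediction bands, and
point exclusion for an autofluorescence-elevated monomer).

Background corrections: a non-fluctuating background count rate $k_B$
dilutes brightness as $\eta_{app} = \eta (k - k_B)/k$ — the amplitude of the
correlation scales with the squared signal fraction while the rate scales
linearly. Fluctuating background species combine as the brightness-squared
weighted mean
$\eta_{app} = (\eta^2 N + \sum_b \eta_b^2 N_b)/(\eta N + \sum_b \eta_b N_b)$,
always between the dimmest and brightest species present. The analysis
pipeline applies the count-rate correction with the dark rates carried in
the photon-file header (dark subtraction by measured rates rather than an
off-peak window, because the format records them).

Two-photon geometry: $\tau_D = \omega^2/(8D)$ links the correlation time to
the diffusion coefficient, so a standard of known $D$ (fluorescein,
300 µm²/s at room temperature) calibrates $\omega$; the effective volume is
$V = \pi^{3/2}\, \omega^2 z / 8$, and $\langle N\rangle / (N_A V)$ converts
occupancy to concentration. With $\omega = 424$ nm and $z = 2.8$ µm this
gives 0.35 fl; note that at the low-power geometry (367 nm, 3.7 µm) the
formula gives 0.347 fl, which prints as 0.35 at two decimals — published
values rounded from unrounded inputs can differ in the last digit.

## The hetero-FRET pairing model

If a fraction $p$ of subunits carries a donor and $1-p$ an acceptor and
subunits pair at random, donor–donor pairs occur at $p^2$, mixed pairs at
$2p(1-p)$, and only donors in mixed pairs transfer (pairwise efficiency
$E$). The donor-averaged observed efficiency is then linear,
$E_{obs} = E (1 - p)$: intercept and negated slope both estimate $E$, and
their agreement is the signature of exclusive 1:1 pairing.
`fit_pairing_model()` reports both, plus a consistency z-statistic that
warns beyond $3\sigma$ (a flat $E_{obs}(p)$ — unpaired subunits or purely
collisional FRET — trips it). Regression is unweighted by default since
per-cell uncertainties are rarely available; weights are accepted.

One subtlety the Monte-Carlo twin (`simulate_random_pairing()`) exposes: at
a handful of pairs, the *conditional* expectation of the per-realization
donor average (given at least one donor) is not $E(1-p)$; the exact identity
holds for the donor-weighted (pooled) average, which is what the function
returns and what the enumeration oracle in the tests computes. The fit's
nominal 95% confidence intervals cover the truth in over 90% of synthetic
replicates.

Only the paired 1 donor : 1 acceptor topology is modelled; ring or
multi-neighbour transfer topologies are out of scope, and the fit reports
raw intercepts (no collisional-FRET baseline subtraction) so a small
non-zero negative-control intercept remains visible to the user.

## What the simulator emulates — and what it does not

`simulate_stream()` generates photon records with full ground truth:

* **Diffusion**: each complex takes per-axis Gaussian steps of SD
  $\sqrt{2 D\, dt}$ in a periodic box with half-widths
  `box_multiplier` × $(\omega, \omega, z)$ (default 4; the box then holds
  ≈ 735 molecules per molecule in the observation volume). The propagation
  step must satisfy $dt \le \tau_D / 50$.
* **Detection**: Poisson emission with the squared-Gaussian two-photon
  weight $W = e^{-4(x^2+y^2)/\omega^2} e^{-4z^2/z^2_0}$. This convention
  makes $\int W\,dV$ equal the closed-form volume above and the fitted
  $\tau_D$ obey $\omega^2/(8D)$ exactly. The correlation amplitude constant
  implied by $W$ is $2^{-3/2} = 0.354$; fitting with the conventional fixed
  $\gamma = 0.35$ therefore carries a ~1% systematic in
  $\langle N\rangle$ — far below the stochastic tolerances used anywhere.
* **Micro-times**: exponential decay folded modulo the 12.5 ns pulse period
  (80 MHz repetition), quantized to the digitizer grid (default 1024
  channels per period).
* **Polarization**: the channel is drawn with odds
  $(1+2r) : (1-r)/g$ evaluated at the unfolded delay, where $r(t)$ is the
  species' depolarization model
  $r(t) = r_0 e^{-t/\theta}\left[(1-L) e^{-t/\phi} + L\right]$ with plateau
  $L = (1 + (n-1)c)/n$ for $n$ fluorophores and energy-transfer anisotropy
  ratio $c$. Monomers reduce exactly to $r_0 e^{-t/\theta}$. Because the
  two detectors jointly capture a polarization-dependent fraction of the
  emission ($\propto (1+2r) + (1-r)/g$), emitted photons are thinned with
  that weight — this is what makes $F(t)$ exactly mono-exponential and the
  histogram anisotropy exactly $r(t)$. The emission rate is pre-scaled by
  the species' mean detection efficiency so that `peak_brightness_per_fluor`
  is the *detected* brightness: detected concatemer brightness is then
  proportional to $n$, the convention under which normalized brightness
  reads stoichiometry (and the convention in which instrument brightness
  calibrations are quoted).
* **Background**: independent Poisson dark counts per channel with uniform
  micro- and macro-times.
* **Determinism**: everything — including the compiled diffusion kernel —
  draws from R's seeded RNG; identical configs give bit-identical streams.

Default species parameters describe a Venus-like fluorescent protein:
lifetime 3.1 ns, rotational correlation time 16.4 ns, fundamental anisotropy
0.4, homo-FRET exchange time 1 ns (placing the fast anisotropy decay within
the first ~2 ns; no quantitative exchange rate is established for Venus
pairs, so recovered $\phi$ values should be treated as internal to the
simulation, not as validated photophysics).

Not modelled, deliberately: photobleaching, triplet/flicker dynamics
(absent under two-photon excitation), detector dead time and TCSPC pile-up
(a validation warning fires above 100,000 cps, the operating ceiling below
which real acquisitions stay to avoid pile-up), membrane/2-D diffusion, and
cellular geometry. Passing recovery tests therefore demonstrate the
correctness of the estimators and fits on an idealized instrument — they do
not certify behaviour on data afflicted by bleaching or pile-up.

Two known discretization effects, both quantified in development: photon
positions are piecewise-constant within a propagation step, which at
$dt = \tau_D/50$ suppresses the correlation amplitude (hence inflates
brightness estimates) by roughly 2%; it is common-mode across species
simulated at the same $dt/\tau_D$ and cancels in normalized brightness. And
histogram bin widths are snapped to whole digitizer channels — mixing
incommensurate grids imprints a sawtooth on decays that inflates
$\chi^2$ without biasing parameters.

## Problem sizes and statistical design of the test suite

The stochastic tests size their simulations by a precision budget chosen
from measured estimator variance: occupancies $\langle N\rangle$ of 0.8–3,
acquisition lengths of a few thousand correlation times, detected count
rates inside the 20,000–100,000 cps operating envelope, per-fluorophore
detected brightness at the upper range of bright two-photon work
(2×10⁴ cpsm) so each transit carries enough photons, and micro-time
recovery on beam-centre-pinned complexes at ~1–2 million photons (where
diffusion statistics are irrelevant and simulation cost is trivial). Slower
diffusion (correlation times of 0.75–1.1 ms, the large-complex regime) is
preferred for recovery scenarios: at fixed count rate it raises photons per
transit and lowers propagation cost simultaneously. Replicate acquisitions
are curve-averaged before fitting — the same averaging the source
experiments use — because single-acquisition fits at large-complex occupancy
wander along a (⟨N⟩, τ_D, baseline) degeneracy ridge: brightness comes back
to ~2–3% per averaged measurement, while τ_D retains ~15% precision at a
shallow $G(0)$ (occupancy 3) versus ~4% on the high-contrast fluorescein
standard (occupancy 1) — which is where the 10% correlation-time recovery
claim is asserted. The correlation-amplitude law is checked at
$\langle N\rangle \in \{1, 5, 20\}$; higher occupancies add tens of
thousands of simulated molecules for no new information.
Brightness-linearity uses a dedicated monomer reference measured at
$\langle N\rangle = 3$ — brightness is per-molecule, so the reference
concentration is free, and the higher rate cuts its variance roughly
quadratically.

One statistical note: "no correlation anywhere" assertions use segment-based
standard errors estimated from 10 segments, so pointwise $G/\mathrm{SE}$ is
$t_9$-distributed and a strict 3-SE bound on every one of ~70 lags would
fail about half of all clean runs by chance. The tests assert that at least
95% of lags lie within 3 SE and all lags within the Bonferroni-corrected
$t$ quantile — the meaningful reading of "consistent with zero everywhere".

## Defaults table

| Parameter | Default | Where | Why |
|---|---|---|---|
| pulse period | 12.5 ns | `instrument_config()` | 80 MHz mode-locked excitation |
| micro resolution | period/1024 | `instrument_config()` | typical TCSPC ADC depth; always read from the file header, never assumed |
| macro clock | 12.5 ns | `instrument_config()` | one tick per excitation pulse |
| g-factor | 1 | `instrument_config()` | calibrated value for a matched detector pair |
| dark rates | 500 cps each | `instrument_config()` | hybrid-detector ballpark (400–750 cps) |
| γ | 0.35 | `fit_diffusion_model()` | two-photon 3-D Gaussian PSF constant; fixed, never fitted |
| ω/z | 0.15 | `fit_diffusion_model()` | in-vitro calibration value (0.10 at low power) |
| base lag | 1 µs | `multitau_correlate()` | ≪ any correlation time of interest |
| points/octave | 8 | `multitau_correlate()` | standard multi-tau density |
| segments | 10 | `multitau_correlate()` | SE estimation; ≥ 5 needed |
| fit lag window | [base, duration/100] | `fit_diffusion_model()` | keeps the normalization-bias-dominated tail out |
| anisotropy window | peak + 0.5 ns → end | `fit_exponential_decay()` | tail fit, no IRF deconvolution |
| χ² improvement to add a component | > 20% | `select_exponential_model()` | prefer the simpler decay model |
| fluorescein D | 300 µm²/s | `fpfa_calibrate()` | room-temperature standard for waist calibration |
| box multiplier | 4 | `simulation_config()` | periodic images negligible (detection weight ~e⁻⁶⁴ at the wall) |
| dt | τ_D/50 | `simulation_config()` | resolves transits; coarser steps refused |

## Limitations

* Single diffusing component only; mixtures bias $\tau_D$ and $\eta$ toward
  brightness-squared-weighted averages (the background model quantifies the
  brightness side of this).
* Tail fitting cannot resolve decay components much faster than ~100 ps or
  comparable to the digitizer bin.
* Normalized brightness counts *mature, fluorescent* tags: dark or immature
  fluorophores, or unlabeled endogenous subunits, make it a lower bound on
  true stoichiometry.
* The pairing fit cannot distinguish one pair per complex from several
  pairs per complex — it reads the pairwise efficiency, not the pair count.
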