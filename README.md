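# antennafcs

Quantifying protonation dynamics at lipid membrane surfaces from
fluorescence correlation spectroscopy (FCS).

Membrane surfaces can act as *proton-collecting antennas*: protons adsorb to
the lipid headgroup region, diffuse laterally, and reach a membrane-bound
acceptor far faster than direct collisions from bulk water would allow. FCS
makes this measurable at steady state — a pH-sensitive dye (fluorescein)
anchored to a lipid nanodisc blinks as it protonates and deprotonates, and
the blinking kinetics appear as a dark-state relaxation in the intensity
autocorrelation function. `antennafcs` is for biophysicists who want to turn
such correlation curves into protonation rate constants and to explore the
underlying surface-exchange kinetics in simulation.

## What the package computes

**Correlation model.** The autocorrelation of a freely diffusing fluorophore
with three independent dark states (protonated, triplet, redox):

```
G(tau) = 1/(N (1-P-T-R)) * (1 + tau/tau_D)^-1 * (1 + tau/(beta^2 tau_D))^-1/2
         * (1-P-T-R + P e^(-tau/tau_prot) + T e^(-tau/tau_T) + R e^(-tau/tau_R)) + 1
```

with mean occupancy `N`, diffusion time `tau_D`, axial/lateral ratio `beta`,
dark-state fractions `P`, `T`, `R` and relaxation times `tau_prot`, `tau_T`,
`tau_R`.

**Global fitting.** `fit_fcs()` fits single curves or whole pH/buffer series
by Levenberg–Marquardt least squares, with diffusion and photophysics
parameters shared across curves and `N`, `P`, `tau_prot` per curve —
the standard global-analysis protocol when only the protonation state varies
between conditions.

**Kinetics.** For a one-step protonation reaction,
`k_prot = 1/tau_prot = k_off + kappa_on [H+]`. `fit_protonation()` extracts
the second-order on-rate constant `kappa_on` (slope) and the deprotonation
rate `k_off` (intercept) from `k_prot` versus `[H+]`. `fit_titration()` fits
the two-pKa brightness titration
`NMB = a/(1+10^(pKa1-pH)) + (1-a)/(1+10^(pKa2-pH)) + c`, and
`antenna_radius()`/`dwell_time()` implement the 2D mean-square-displacement
relation `R_PCA = sqrt(2 D_s tau_s / pi)`.

**Monte Carlo antenna model.** `simulate_antenna()` is a kinetic Monte Carlo
simulation of three proton-exchange pathways on a nanodisc: (I) adsorption to
and buffer-enhanced desorption from the membrane surface, (II) 2D surface
diffusion with capture by the central fluorophore, and (III) direct
bulk/buffer exchange with the fluorophore. `sweep_buffer()` and
`sweep_disc_size()` reproduce the characteristic non-monotonic buffer
dependence of `k_prot` (minimum near 3 mM phosphate) and the saturation of
the antenna effect with membrane area.

**Synthetic data.** `generate_ph_series()` creates seeded benchmark curve
series at the bundled sample parameter sets (`fluorescein_samples()`), with
ground truth carried in a manifest — the basis for all closed-loop tests.

## Worked example

Generate a 10-point pH series for fluorescein on a 12-nm nanodisc, fit it
globally, and extract the protonation rate constants:

```r
library(antennafcs)

spec   <- sample_spec("ND12-flu")
series <- generate_ph_series(spec, seq(8, 9, length.out = 10),
                             noise_eps = 0.02, seed = 7)
fit <- fit_fcs(series$curves,
               apply_triplet_bounds(fit_spec(fixed = list(beta = 5),
                                             weights = "g_sd")))
fit
#> <fcs_fit> 10 curve(s), 1280 points, cost 1181.31
#> shared: tau_D=0.0003993, T=0.2748, tau_T=1.5e-06, R=0.03728, tau_R=6.806e-05

rates <- fit_protonation(kprot_points(fit), h_max = 1e-8)
rates
#> <protonation_fit> kappa_on = 7.474e+12 1/(M s) (SE 5.19e+11), k_off = 47670 1/s (SE 2586), n = 10
```

The recovered `kappa_on` of 7.47e12 1/(M s) is within 2% of the generating
value (7.35e12) and about 190-fold above the free-dye value of 4e10 —
the proton-collecting antenna enhancement. The shared photophysics land in
the calibrated triplet window (`T` 24–28%, `tau_T` 1.4–1.5 us).

Geometry helpers put numbers on the antenna itself:

```r
antenna_radius(D_s = 2e7, tau_s = 1e-6)  # 3.57 nm
annulus_area(12, 6.5)                    # 79.9 nm^2 of lipid around the protein
```

`autoplot()` methods exist for fits, rate-law regressions and Monte Carlo
sweeps; `tidy()`/`glance()`/`augment()` give tabular access to every result.

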