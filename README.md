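# chromodwell

Quantifying how long a chromatin-binding protein stays on chromatin —
and how much of it is bound at all — from live-cell single-particle
tracking (SPT), plus a binomial fragment-match score for assigning
citrullination sites in tandem mass spectra. The package was built
around the analysis of HP1γ (heterochromatin protein 1 gamma) dynamics
in mouse embryonic stem cells, where citrullination of two chromodomain
arginines modulates chromatin binding, but every stage is generic.

It is aimed at quantitative cell biologists and microscopists who have
(or want to simulate) SPT movies of nuclear factors, and at proteomics
users who need a transparent reimplementation of the localization-
probability score for arginine citrullination.

## What it computes

**Jump-distance (JD) mixture analysis** — fast-frame SPT (13.5 ms)
displacements are fit with a mixture of 2D Brownian components,

P(r) = Σᵢ fᵢ (1 − exp(−r² / (4 Dᵢ Δt))),

giving diffusion coefficients Dᵢ and fractions fᵢ; components with
D ≤ 0.1 µm²/s are classified *bound*, D ≥ 0.6 µm²/s *diffusing*.

**Residence-time analysis** — long exposures (500 ms) blur out
diffusing molecules (*motion blurring*), so only bound molecules are
tracked. Track-survival data are fit with an exponential mixture

F(t) = Σᵢ fᵢ exp(−t/τᵢ),

separating *unspecific* (short-τ) from *specific* (long-τ) binding.
The number of components (1–3) is chosen by the lowest
BIC = ln(n)(p+1) + n(ln(2π·RSS/n) + 1), and parameter uncertainty
comes from a 1000× parametric bootstrap. Conditions are compared with a
Z-test on replicate-level estimates.

**Detection, tracking, simulation** — band-pass / rolling-ball spot
detection with brightness-weighted centroids and size/SNR gates,
globally optimal nearest-neighbour linking within 6 px (936 nm), and a
full generative simulator (two-state Brownian motion, dwell mixtures,
photobleaching, PSF rendering with Poisson noise and motion blur onto
16-bit TIFF movies) so the whole pipeline can be validated against
ground truth.

**PTM site localization** — for a peptide carrying citrullines
(arginine + 0.984016 Da), every placement over the candidate arginines
is scored against the top-10-peaks-per-100-amu filtered spectrum:
p = C(n,k)·0.04ᵏ·0.96ⁿ⁻ᵏ for k matched of n theoretical b/y ions at
20 ppm, score = −10·log₁₀(p); configuration weights ∝ 1/p give
per-site localization probabilities.

## Worked example

```r
library(chromodwell)

# residence times: 5000 synthetic dwells, 88% x 2.4 s + 12% x 28.8 s
d   <- simulate_dwell_times(data.frame(fraction = c(0.88, 0.12),
                                       tau = c(2.4, 28.8)), 5000, seed = 1)
fit <- select_dwell_model(survival_curve(d))
fit <- parametric_bootstrap(fit, n_boot = 1000, seed = 1)
print(fit)
#> Residence-time exponential mixture: 2 component(s), 5000 dwells (grid 0.5 s)
#>   tau1 = 2.296 s  (fraction 0.8716)  [bootstrap 2.294 +/- 0.04569 s]
#>   tau2 = 27.74 s  (fraction 0.1284)  [bootstrap 27.3 +/- 1.5 s]
#>   RSS 0.04364, BIC -3455 (binned target), 1000 bootstrap refits

# jump distances: 10,000 jumps, D = 0.02 / 1.5 um^2/s, 37.4% bound
j <- simulate_jumps(10000, data.frame(D = c(0.02, 1.5),
                                      fraction = c(0.374, 0.626)),
                    dt = 0.0135, seed = 1)
print(select_jd_model(j))
#> Jump-distance mixture fit: 2 component(s), 10000 jumps at dt = 0.0135 s
#>   D1 = 0.02052 um^2/s  (fraction 0.3759)
#>   D2 = 1.487 um^2/s  (fraction 0.6241)
#>   bound 37.6%, diffusing 62.4%;  RSS 7.047e-05, BIC -1114

# citrullination localization on the chromodomain peptide
print(site_probabilities(nondiscriminating_spectrum("VLDRRVVNGK", 1)))
#> PTM localization for VLDRRVVNGK (+1 citrulline)
#>   site probabilities: R4 = 0.5, R5 = 0.5
#>   2 configurations scored; best score 202.18
```

Reading the output: BIC selected two binding modes; the bootstrap
recovers the unspecific residence time 2.4 s and the specific 28.8 s
(here 2.29 ± 0.05 s and 27.3 ± 1.5 s) and the 12% specific fraction.
The JD fit recovers the two diffusion populations and the 37.4% bound
fraction. For the peptide spectrum containing no ion that distinguishes
its two adjacent arginines, the citrulline is split 0.50/0.50 between
them.

`simulate_trajectories()` → `render_movie()` → `localize_movie()` →
`link_localizations()` → `compute_jumps()` / `compute_dwells()` runs
the same analyses from rendered movies instead of idealized samples. A
thin command-line wrapper over these functions is in
`inst/cli/chromodwell.R`.

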