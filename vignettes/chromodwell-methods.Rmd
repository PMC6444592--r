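---
title: "Models and methods behind chromodwell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromodwell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromodwell)
```

chromodwell analyses live-cell single-particle tracking (SPT) of
chromatin-binding proteins such as HP1&gamma;, and scores citrullination
site assignments from tandem mass spectra. This vignette describes the
models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not
emulate.

## The two-regime SPT experiment

A chromatin reader like HP1&gamma; alternates between free 3D diffusion
and binding to chromatin. Two acquisition regimes probe the two sides of
this equilibrium:

* **Fast imaging** (13.5 ms/frame): both bound and diffusing molecules
  are visible. The distribution of frame-to-frame displacements ("jump
  distances") is fit with a mixture of 2D Brownian components to
  estimate diffusion coefficients and population fractions.
* **Slow imaging** (500 ms exposure): diffusing molecules spread their
  photons over roughly `sqrt(4 D t_exp)` (about 1.7 &micro;m for
  D = 1.5 &micro;m&sup2;/s), falling below the detection gates — this is
  *motion blurring*. Only bound molecules remain visible, and the
  distribution of their track durations estimates chromatin residence
  times.

## Jump-distance mixture model

For a molecule with diffusion coefficient $D$ observed at lag
$\Delta t$, the probability that it moves less than $r$ is

$$P(r) = \sum_i f_i \left(1 - e^{-r^2 / (4 D_i \Delta t)}\right),
\qquad \sum_i f_i = 1 .$$

`fit_jd()` estimates $(D_i, f_i)$ by least squares. The default target
is the jump-distance *histogram* (100 equal-width bins to the 99.9th
percentile plus a catch-all tail bin); the empirical cumulative curve is
available via `target = "cdf"`. The histogram is the default because
model selection (below) compares residual sums of squares, and histogram
bin counts are close to independent, whereas cumulative-curve residuals
are long-range correlated: with correlated residuals an extra mixture
component can absorb sampling wiggles and spuriously halve the RSS, so
selection over-fits. With binned residuals the RSS improvement from a
spurious component is of the order of its two extra degrees of freedom
and the BIC penalty wins. Parameter estimates from the two targets agree
closely on well-sampled data.

Components with $D \le 0.1$ &micro;m&sup2;/s are classified bound and
$D \ge 0.6$ &micro;m&sup2;/s diffusing (`classify_fractions()`);
anything between is reported as intermediate. The apparent $D$ of the
bound population contains a localization-noise floor
$\sigma_{loc}^2/\Delta t$; no correction is applied, matching common
practice, and the floor is below 0.07 &micro;m&sup2;/s for the default
30 nm noise at 13.5 ms.

Constraints are enforced by parameterization: $\log D_i$ for
positivity, and fractions as normalized positive weights so they stay
on the simplex. Multi-start initialization uses quantile-based $D$
guesses (the $r$ quantiles at 25/50/75% converted through the
single-component median relation $r_q^2 = 4 D \Delta t \ln(1/(1-q))$).

## Residence-time mixture model

Track durations in the slow regime are summarized as a survival curve
on the acquisition grid, $S(t_j)$ = fraction of trajectories lasting at
least $t_j = j\,\Delta t$, and fit with

$$F(t) = \sum_i f_i\, e^{-t/\tau_i}, \qquad \sum_i f_i = 1,$$

with 1–3 components. In a two-component fit the short-$\tau$ mode is
*unspecific* binding and the long-$\tau$ mode *specific* binding.

`fit_exponential_mixture()` fits the per-frame *increments* of the
survival curve (the binned dwell distribution) by weighted least
squares. Bin fractions are binomial with variance approximately
$p_j/n$, which spans three orders of magnitude between the head and the
tail of the distribution; the fit therefore weights each bin by the
inverse of its variance, with the weights refreshed from the fitted
model over three reweighting rounds (weights from the *empirical*
fractions would give empty tail bins enormous weight and bias the slow
component low). This iteratively reweighted binned fit is essentially a
Gaussian approximation to the multinomial likelihood: it keeps the
residuals near-independent with near-constant standardized variance —
the assumptions under which the RSS-based BIC below is a valid model
comparison — while retaining full sensitivity to the sparse tail that
pins down the specific residence time. A plain unweighted fit to the
cumulative survival curve is available via `target = "survival"`; it
estimates parameters well but is not used for selection, for the
correlation reason above.

Right-censored dwells (trajectories still present in the movie's last
frame) are excluded from the curve; with movies much longer than the
slowest $\tau$ this bias is negligible, and the censored count is
reported. No photobleaching correction is applied; if the bleaching
rate is comparable to $1/\tau_2$ the fitted residence times are
underestimates. The dwell convention is $(n-1)\Delta t$ for an
$n$-point track (the time between first and last observation); the
$n\Delta t$ alternative is a flag on `compute_dwells()`. Because an
$(n-1)$-frame dwell is observed exactly when the true dwell covers $n$
exposures, the measured survival curve is the true one shifted by one
frame; this affects the fitted fractions at the percent level and the
time constants negligibly.

## Model selection and uncertainty

The number of components (1–3) is chosen by the Bayesian Information
Criterion computed from the residual sum of squares,

$$\mathrm{BIC} = \ln(n)\,(p+1) + n\left(\ln\frac{2\pi\,\mathrm{RSS}}{n} + 1\right),$$

with $n$ the number of fitted points (bins) and $p = 2K - 1$ free
parameters for $K$ components; the lowest BIC wins
(`select_dwell_model()`, `select_jd_model()`). This is the Gaussian
least-squares BIC including the implicit noise-variance parameter
(hence $p+1$); the conventional $n\ln(\mathrm{RSS}/n) + p\ln n$ form is
available as `variant = "textbook"` in `bic()` and ranks models
identically for fixed $n$.

Parameter uncertainty comes from a parametric bootstrap
(`parametric_bootstrap()`, default 1000 replicates): synthetic dwell
datasets of the original sample size are drawn from the fitted mixture
and refit with the same number of components, and the per-parameter
bootstrap mean and SD are attached to the fit. Bootstrap refits reuse
the base fit as the starting point and fix the variance weights at the
generating model's values, which keeps 1000 refits to well under a
minute at $n = 5000$. Conditions (for example wild-type vs mutant, or
&plusmn;LIF) are compared on replicate-level parameter estimates with a
two-sided Z-test (`compare_conditions()`).

## Detection and tracking

Fast-mode detection (`detect_puncta(mode = "fast")`) band-pass filters
each frame with a difference of Gaussians (defaults: noise scale 1 px,
background scale 5 px; separable convolution with replicate boundary so
a flat field maps exactly to zero), takes 8-neighbourhood local maxima
(ties broken toward the lower (row, col)), and estimates sub-pixel
positions by brightness-weighted centroid in a 7&times;7 window refined
by an iterative Gaussian-mask centroid — the refinement removes the
~0.1 px truncation bias of a plain windowed centroid without resorting
to PSF fitting. Gates: spot FWHM < 3 px (second-moment estimate on the
background-subtracted raw window, since the band-pass reshapes spots)
and SNR > 8, with SNR = (peak &minus; annulus median) / robust annulus
SD; both gate thresholds are parameters. Slow-mode
detection replaces the band-pass with rolling-ball background
subtraction (grayscale opening with a 5 px disc) and a fixed global
intensity threshold, default 25,000 counts — the threshold is on the
simulator's 16-bit scale and deliberately configurable, since its
original scale (raw vs background-corrected ADU) is
instrument-specific.

Localizations are linked frame-to-frame within a 6 px (936 nm at
156 nm/px) radius by a globally optimal one-to-one assignment
(Hungarian algorithm) that maximizes the number of links and then
minimizes summed distance: non-assignment is priced at one radius per
endpoint, so any within-radius link is cheaper than leaving both ends
open. There is no gap closing — a missed frame terminates a trajectory,
which is conservative for residence times. Linking is deterministic and
is verified in the tests against exhaustive enumeration on small
scenes.

## What the simulator emulates (and what it does not)

`simulate_trajectories()`/`render_movie()` generate two-state Brownian
motion with per-axis increment variance $2 D \, dt$ at ten sub-steps
per exposure, exponential-mixture dwell times for bound molecules,
exponential photobleaching, Gaussian localization noise on reported
positions, and Poisson-noise movie frames in which photons are spread
along the sub-step path (motion blur). Defaults are the study
conditions: 156 nm pixels, 13.5 ms or 500 ms frames,
$D_{bound} = 0.02$ and $D_{free} = 1.5$ &micro;m&sup2;/s, 37.4% bound,
dwell mixture 88% &times; 2.4 s + 12% &times; 28.8 s (the slow fraction
is the midpoint of the reported 10–13% band). Pixel size, PSF width
(170 nm), photon budgets and background are not reported quantities;
they are declared defaults chosen to give SNR comfortably above the
detection gates, not values inferred from data.

Deliberate simplifications: bound molecules diffuse slowly rather than
sitting still (their reported $D$ is apparent, including chromatin
motion); an unbinding molecule is censored rather than re-entering the
diffusing pool; no photoactivation scheduling, 3D motion, anisotropic
PSF, or EMCCD gain model beyond Poisson noise. Reported per-frame
positions are instantaneous mid-exposure positions, so simulated jumps
follow the Brownian law exactly — the photon-weighted blurring that
shrinks apparent jumps in real long-exposure data appears only in the
rendered movies. Passing recovery tests on these simulations therefore
demonstrates correctness of the estimators under the stated model, not
robustness to real-data pathologies such as drift, variable background,
or fluorophore blinking within a frame.

Problem sizes used in the recovery checks — 5000 dwell times, 10,000
jumps, 1000 bootstrap refits, three replicates of 2000 dwells for the
condition-level comparison — mirror the data volumes of the motivating
experiments (>5000 fast-mode trajectories; >1000 slow-mode
trajectories; bootstrap of 1000).

## Citrullination site localization

Citrullination converts arginine to citrulline (+0.984016 Da). For a
LysC peptide carrying $m$ citrullines with several candidate arginines,
`site_probabilities()`:

1. filters the spectrum to the 10 most intense peaks per 100 amu
   window;
2. enumerates every placement of the $m$ citrullines over the candidate
   arginines;
3. for each configuration, generates singly charged b/y ions (HCD
   fragmentation; no neutral losses) restricted to the observed mass
   range, counts matches $k$ out of $n$ theoretical ions at 20 ppm
   (nearest-first, one peak per ion), and scores
   $p = \binom{n}{k} 0.04^k\, 0.96^{\,n-k}$,
   score $= -10 \log_{10} p$;
4. converts scores to configuration probabilities with weights
   $\propto 1/p$ (equivalently $10^{\text{score}/10}$), normalized over
   configurations; a site's probability is the summed weight of
   configurations containing it.

Choices worth noting: the binomial coefficient is the standard
$\binom{n}{k}$ and the full binomial pmf is used by default (a
truncated $\binom{n}{k} 0.04^k$ variant is provided behind
`full_binomial = FALSE` for compatibility with abbreviated statements
of the score); $n$ counts all in-range theoretical ions of the
configuration, not only site-discriminating ones; candidate sites are
arginines only. When no matched ion discriminates between two candidate
sites the two configurations score identically and each site receives
exactly 0.50 — the worked example for the chromodomain peptide
VLDRRVVNGK, whose two adjacent arginines are separated only by the b4
and y6 ions.

## Degenerate inputs and numerical edges

* A mixture component with $D = 0$ is a step at $r = 0$ in the JD CDF.
* `bic()` refuses RSS = 0 (an interpolating fit has no noise scale);
  fits clamp RSS at 1e-300 before the call.
* Optimization failures at one start fall back to the remaining starts;
  a model that converges at no start is dropped from selection with an
  error only if no model converges at all.
* More than 10% failed bootstrap refits abort the bootstrap.
* Detection returns an empty table for an empty frame but errors on
  NaN pixels; candidate maxima too close to the border for a full
  centroid window are discarded.
* All stochastic entry points (`simulate_*`, `parametric_bootstrap`,
  `synth_spectrum`) are reproducible bit-for-bit under a fixed seed.

## Known limitations

* Censored-dwell exclusion and the absence of a bleaching correction
  bias residence times low when movies are short or bleaching is fast;
  the config exposes the bleach rate so users can simulate the size of
  the effect for their regime.
* The linker has no gap closing or merge/split handling, so blinking
  fluorophores fragment trajectories.
* The JD model assumes pure Brownian motion; anomalous diffusion and
  state switching within a trajectory are out of scope.
* The PTM scorer localizes a fixed number of citrullines on a given
  peptide; it is not a database search and performs no FDR control.
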