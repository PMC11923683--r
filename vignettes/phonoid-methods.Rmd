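---
title: "Golden-Ratio stimuli and proteinoid signal analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Golden-Ratio stimuli and proteinoid signal analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonoid)
```

Proteinoids — thermal proteins that self-assemble into micron-scale
microspheres — behave electrically like leaky capacitive membranes, and
there is ongoing interest in whether mathematically structured stimuli
(Fibonacci sequences, Golden-Ratio scalings) are processed differently from
arbitrary ones. `phonoid` implements the full computational chain for such
experiments: stimulus synthesis, a capacitive response model, a
signal-metric and information-theoretic analysis battery, a
signal-modulated Brownian particle simulator, trajectory statistics, and
microsphere morphometry. A seeded synthetic-data generator takes the place
of laboratory recordings so every stage is testable offline.

This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and the limits of what the synthetic validation
shows.

## Stimuli

**Voltage sequences.** Two discrete sequences are generated with 0-based
step index $n$:

* inverse-Fibonacci: $V(n) = V_0 / F(n+1)$ with $F(1)=F(2)=1$. Fibonacci
  numbers are carried in exact arbitrary-precision integer arithmetic
  (base-$10^7$ limbs) because terms such as $F(1000)$ (209 digits) overflow
  every native type; `fibonacci_numbers()` offers a double-precision
  variant that is exact through $F(78) < 2^{53}$.
* Golden-Ratio decay: $V(n) = V_0\,\varphi^{-n/s}$ with
  $\varphi = (1+\sqrt5)/2$ and scale $s$ (default 100, which stretches the
  decay so that 1000 steps starting at 10 V end at
  $10\,\varphi^{-9.99} \approx 0.0817$ V). On a log axis the sequence is a
  straight line of slope $-\ln\varphi/s$ per step, which the tests verify
  to $10^{-12}$ relative error.

The 0-based indexing convention is deliberate: the printed endpoint of the
10 V/1000-step decay corresponds to exponent $-9.99$, i.e. last index 999,
and the package adopts that convention uniformly.

**Tone bank.** One sinusoid per Fibonacci frequency
(144, 233, 377, 610, 987, 1597 Hz), 5 s each by default, plus a combined
stimulus renormalized to peak amplitude 1. Pre-normalization amplitudes
default to equal weights: the measured spectral roll-off in recordings of
this kind is small enough (tens of percent across the set) that we
attribute it to acquisition rather than synthesis, and the weights remain a
parameter for users who disagree. The combined file can be formed by
superposition (`mode = "sum"`, the default, matching the additive synthesis
definition) or concatenation (`mode = "concat"`), since either reading of
"combined" is defensible; both are tested.

**Fractal soundscape.** Additive synthesis over the geometric progression
$f_k = f_0\varphi^k$, $k = 0..10$, $f_0 = 220$ Hz, each component with a
random phase drawn uniformly from $[0, 2\pi)$ by one seeded generator per
call. With a 44.1 kHz rate the top harmonic ($220\,\varphi^{10} \approx
27.1$ kHz) exceeds Nyquist; such components are dropped with a warning
rather than folded, because aliased energy would corrupt the spectral
analyses downstream. The amplitude-modulation law is not fully pinned down
by its source, so the package uses the simplest envelope with a
configurable depth $d$:
$z_\mathrm{mod}(t) = z(t)\,[1 - d/2 + (d/2)\sin(2\pi f_\mathrm{mod} t)]$,
$f_\mathrm{mod} = f_0/\varphi^5 \approx 19.84$ Hz; $d = 1$ gives the
half-raised sine $(1+\sin)/2$ with mean $\tfrac12$. Output is normalized to
$[-1, 1]$.

**Serialization.** CSV (`index,value` for stepped sequences,
`time_s,value` for sampled signals) and mono 16-bit PCM WAV. The WAV
reader/writer is a minimal RIFF implementation over `readBin`/`writeBin`;
round trips are exact to the 1-LSB quantization of the format.

## Capacitive response model

The proteinoid is modelled as an RC system with time constant
$\tau = RC$; the reference parameters $R = 128\ \Omega$,
$C = 2.888\ \mu\mathrm{F}$ give $\tau = 369.664\ \mu$s. The charging
response to the $\varphi$-decay stimulus is
$$V_c(t_n) = V_0\,\varphi^{-n/s}\,(1 - e^{-t_n/\tau}), \qquad t_n = n\,\Delta t.$$
The formula mixes a step index (in the $\varphi$ exponent) with physical
time (in the charging factor); the package keeps both explicit — the
exponent uses $n/s$ and the charging uses $t_n = n\,\Delta t$ with
$\Delta t$ a visible parameter (default 1 ms) — rather than asserting a
unit identification the source never prints. With $s \to \infty$ the
expression reduces to the textbook step response, which the tests use as a
limit check.

Impedance uses the parallel-RC form
$|Z| = R/\sqrt{1 + (2\pi f R C)^2}$, $\theta = -\arctan(2\pi fRC)$:
parallel rather than series topology because the measured DC value equals
$R$ and $|Z|$ must fall below $R$ with frequency. Note that with
$\tau = 369.664\ \mu$s this model gives $|Z| \approx 116\ \Omega$ and
$\theta \approx -25^\circ$ at 200 Hz; reported pairs like
$(89\ \Omega, -42^\circ)$ are not reachable from that $\tau$ under either
RC topology, so the package reproduces the model, not those figures.

The modified Hodgkin–Huxley conductance sometimes mentioned alongside this
model has no published functional form and is out of scope.

## Signal metrics

All estimators operate on uniformly sampled signal tibbles (`time`,
`value`) and are invariant to a common time offset.

* **SNR**: $10\log_{10}(P_x/P_e)$ with the noise fixed as
  $e = y - x$ (output minus input). Identical signals return an `Inf`
  sentinel flagged `zero_noise`.
* **Welch PSD**: Hann window, 50 % overlap, per-segment mean detrend,
  segment length $\min(1024, N/4)$ rounded down to a power of two. Density
  scaling is one-sided so $\sum S(f)\,\Delta f$ recovers the variance of a
  zero-mean signal; a white-noise Parseval check within 10 % is part of the
  acceptance suite. No Welch estimator exists in the R stack this package
  targets, so the averaged periodogram is implemented here directly on
  `stats::fft`.
* **Cross-correlation**: full discrete correlation; the normalized variant
  removes means and divides by $\sqrt{\sum x^2 \sum y^2}$ (global
  coefficient normalization, not per-lag), bounding values in $[-1,1]$.
  Positive lag means the output is delayed relative to the input.
* **Error metrics**: RMSE, MAE, Pearson $r$, and
  $\mathrm{PSNR} = 20\log_{10}(\max|x|/\mathrm{RMSE})$ — the standard
  definition with the stimulus peak as reference, chosen because no
  explicit formula is published for this pipeline.
* **Frequency/impulse response**: $\hat H = S_{xy}/(S_{xx} +
  \varepsilon\max S_{xx})$ from Welch cross- and auto-spectra
  ($\varepsilon = 10^{-8}$ by default, guarding empty bands), inverted to a
  real kernel by Hermitian extension and inverse FFT. With a rectangular
  full-length window and $\varepsilon \to 0$ the round trip recovers an FIR
  kernel to $10^{-6}$, a test-suite invariant.
* **Bispectrum**: direct estimator
  $B(f_1,f_2) = \langle X(f_1)X(f_2)X^*(f_1+f_2)\rangle$ over Hann-windowed
  segments. Quadratic phase coupling yields a peak at $(f_1,f_2)$; with
  independent phases the residual decays only like
  $1/\sqrt{n_\mathrm{seg}}$, so suppression tests average hundreds of
  segments.
* **Spectrogram**: Hann-window STFT magnitude returned as a long tibble.
* **Paired t-test**: two-sided on sample pairs; zero-variance differences
  return a flagged degenerate p-value (1 for identical signals).

## Information dynamics

All information measures are histogram plug-in estimators in bits, with
equal-width bins over the data range, $n_\mathrm{bins} = 16$ by default
(Freedman–Diaconis optional). The plug-in MI is biased upward by about
$(B-1)^2/(2N\ln 2)$ under independence; a Miller–Madow correction is
available and is what the Gaussian-recovery checks use (32 bins,
$N = 10^5$, within 10 % of $-\tfrac12\log_2(1-\rho^2)$ for
$\rho \in \{0.3, 0.6, 0.9\}$). Binned MI of continuous variables
necessarily undershoots the differential closed form when bins are coarse;
16 bins lose ~0.15 bits at $\rho = 0.9$, which is why the calibration uses
32.

Transfer entropy uses embedding $k = l = 1$ with unit lag — a documented
limitation, adopted because no embedding is published for this analysis.
On a binary lag-1 copy channel the estimator reaches 1 bit forward and ~0
backward, the directionality check of the acceptance suite.

Band-limited variants filter both signals with a zero-phase
(forward–backward) Butterworth filter — order 4 for low/high-pass edges,
order 2 per edge for band-pass — before applying the measure; a half-open
band `c(100, Inf)` acts as a high-pass at 100 Hz. Coherence is Welch-based
magnitude-squared coherence and requires at least 8 segments, since a
single segment degenerates to $\gamma^2 \equiv 1$. Normalized per-band MI
is $I(X_f;Y_f)/H(X_f)$ with entropy and MI taken from the same histogram;
a constant filtered input (zero entropy) is flagged `NA`.

The capacity bound $I_{\max} = \log_2(1+\mathrm{SNR})$ and the transfer
efficiency $\eta = 100\,I/I_{\max}$ are arithmetic; the reference pair
$I = 0.0801$ bits, $I_{\max} = 1.23$ bits gives $\eta = 6.5\,\%$. (That
$I_{\max}$ is itself inconsistent with an SNR of 0.19 dB under the bound —
which would give 1.03 bits — so the efficiency is defined on the MI pair,
not derived through the SNR.)

## Particle dynamics

Microspheres follow the Euler–Maruyama discretization of
$$d\mathbf r_i = \alpha\,S(t)\,\hat{\mathbf u}_i\,dt + \sigma\,d\mathbf W_t,$$
where $S(t)$ is the normalized stimulus and $\hat{\mathbf u}_i$ a fixed
random unit heading per particle. The scalar drift $\alpha S(t)$ needs a
direction to act on a 2-D position; per-particle fixed headings keep the
ensemble isotropic while letting the signal modulate each particle's speed,
and make pairwise distances exactly invariant under the common-drift limit.
Defaults: 100 particles uniformly seeded in a 1000 × 1000 nm box,
$dt = 0.01$ s, $t_\mathrm{end} = 50$ s, reflecting boundaries (periodic
optional), $\sigma = 10\ \mathrm{nm}/\sqrt{\mathrm s}$ — chosen so
equilibrium fluctuations of the mean inter-particle distance are a few
percent of its mean.

Ensemble statistics: mean pairwise distance (for uniform points in an
$L\times L$ box the expectation is $0.52141\,L$, the Monte-Carlo-verified
reference for the 1000 nm box — about 521 nm, notably below reported
values near 650 nm, which cannot arise from uniform dispersal in that box
and are therefore not used as a reference), pairwise-distance histograms,
and the distance time series.

## Trajectory statistics

The MSD is the time-and-ensemble average over all overlapping start times
(pure time- or ensemble-averaged modes are available); overlapping windows
were chosen as the variance-minimizing default. `msd(0) = 0` exactly.

The confined-diffusion model $\mathrm{MSD}(\tau) = y_0 + A e^{R_0\tau}$ is
fitted by Levenberg–Marquardt (`minpack.lm::nlsLM`) with geometric initial
values ($y_0$ from the plateau, $R_0$ from the half-saturation lag) and a
small multi-start sweep; fits report $R^2$, adjusted $R^2$, reduced
$\chi^2$, parameter SEs, and the characteristic time $1/|R_0|$ (the
reference rate $-12.90\ \mathrm s^{-1}$ gives 77.5 ms). Degenerate
(constant) curves are flagged rather than fitted. The power-law
(anomalous-diffusion) model $\mathrm{MSD} = K\tau^\alpha$ is fitted in
log–log space; $\alpha = 1$ is normal diffusion, 2 ballistic, $<1$
subdiffusive.

The diffusion coefficient is defined from the exponential model's initial
slope, $D = A R_0 / (2\,\mathrm{dim})$: no published formula connects the
reported $D$ to the printed $(y_0, A, R_0)$ triple, and the initial slope
is the physically meaningful short-time mobility of a saturating MSD.
Fit weighting is unweighted by default with per-lag pair counts available.

Step-size ratios $R_i = |\Delta r_{i+1}|/|\Delta r_i|$ are summarized
against $\varphi$. Ratios with a zero-length denominator step are dropped
and counted (`keep_singular` retains them); summary moments use finite
ratios. For i.i.d. isotropic steps the ratio distribution is
reciprocal-symmetric with median 1, so large means with medians near 1
(as reported for real recordings, e.g. mean ≈ 12 with median ≈ 0.99)
indicate heavy near-singular tails rather than a typical ratio near
$\varphi$.

## Morphometry

Diameter populations are summarized (mean, SD, median, IQR, CV %,
skewness, excess kurtosis) and tested for normality with (a) a plain
Kolmogorov–Smirnov test against $N(\bar x, s)$ — parameters estimated from
the sample, *without* Lilliefors correction, matching the plain-KS usage
this analysis mirrors; the resulting p-values are conservative, which the
tests acknowledge by checking uniformity only against a fully specified
null — and (b) a Jarque–Bera test assembled from sample skewness and
excess kurtosis against $\chi^2_2$, implemented in-package because no
installed dependency provides it, and null-calibrated in the tests.
Q-Q pairs, a Silverman-bandwidth Gaussian KDE and the empirical/fitted CDF
sup-gap complete the battery. Pairwise size ratios are taken
larger/smaller so the $\varphi$ reference is one-sided; for normal
populations with CV ≈ 19 % the modal ratio bin falls in [1.0, 1.2] and
essentially no mass sits near $\varphi$.

## Synthetic data: what it does and does not show

`gen_response_recording` produces
$y = g\,\mathrm{RC}(x) + \mathrm{dc} + \mathcal N(0, \sigma^2)$ with
defaults $g = 0.011$, $\mathrm{dc} = -0.01$ V chosen so the output SD is
about 1 % of the stimulus SD — the attenuation regime of the recordings
this package is designed around. `gen_confined_trajectories` is 2-D
Ornstein–Uhlenbeck motion with stationary per-axis variance $y_0/4$ and
relaxation $|R_0|$, so its ensemble MSD is exactly the saturating
exponential the fitter assumes. `gen_sphere_diameters` draws from the
normal size model ($\mu = 1581.27$, $\sigma = 302.02$ nm; population sizes
default to 200, the order of a typical imaging study, since no count is
published). `gen_golden_walk` is a positive control whose step ratios are
exactly $\varphi$.

Passing tests on these generators demonstrate that the estimators recover
the parameters of data that *obey their own models* — linear MSD for free
diffusion, saturating-exponential MSD for confinement, Gaussian sizes,
linear time-invariant responses. They do not show that real proteinoid
recordings obey those models: real data bring drift, nonstationarity,
electrode artefacts, tracking errors and non-Gaussian noise that the
generators deliberately omit. Published wet-lab values (SNR 0.19 dB,
MI 0.0801 bits, specific Table statistics) depend on the original
recordings and unstated estimator settings and are therefore reproduced as
*definitions*, not as numbers.

## Problem sizes and numerical choices

The validation suite uses sizes at which the statistical properties are
decisive while remaining quick: $2^{15}$ samples for Parseval, $10^5$
samples for MI/TE calibration, 250–400 particles × 200–250 frames for
diffusion recovery (20 seeded replicates for the confined-fit property),
200 replicates for p-value-uniformity checks. Tolerances follow the
estimator, not the example: closed-form identities are checked to
$10^{-9}$–$10^{-12}$, Monte-Carlo recoveries to 2–15 %.

Degenerate inputs are contracts, not accidents: constant signals yield
MI 0 and zero PSD; identical metric pairs yield `Inf` SNR/PSNR sentinels
and degenerate t-tests; all-zero steps, empty bands, single coherence
segments and sub-minimal samples raise typed errors.

## Known limitations

* TE embedding is fixed at $k = l = 1$; slow or multiscale coupling will
  be underestimated.
* Histogram estimators need $N \gg B^2$ ($B^3$ for TE); the defaults are
  not reliable below a few thousand samples.
* The RC model is linear and time-invariant; any voltage-dependent
  conductance of real proteinoid membranes is outside it.
* The particle simulator has no inter-particle interactions,
  hydrodynamics or electrokinetics.
* Plain KS with estimated parameters is conservative (no Lilliefors
  correction), by design.
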