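---
title: "Models and methods behind ribbonflux"
author: "ribbonflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribbonflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribbonflux)
```

## Scope

`ribbonflux` packages the quantitative machinery used to study clathrin
and synaptic-vesicle dynamics at ribbon synapses with live-cell
fluorescence microscopy: fluorescence correlation spectroscopy (FCS) and
its dual-colour cross-correlation variant (FCCS), fluorescence recovery
after photobleaching (FRAP), and event detection in total internal
reflection (TIRF) movies with ribbon-distance geometry. Because the raw
recordings behind such studies are rarely deposited, the package ships
first-class synthetic-data generators with known ground truth; every
analysis stage is validated end to end against them.

## Correlation analysis

### Estimators

For a binned intensity trace $F(t)$ the autocorrelation is estimated in
the zero-baseline convention,

$$g(\tau) = \frac{\langle \delta F(t)\,\delta F(t+\tau)\rangle}
                 {\langle F\rangle^2},\qquad
  \delta F = F - \langle F\rangle,$$

and the two-channel cross-correlation as
$g_{cc}(\tau) = \langle \delta P_1(t)\,\delta P_2(t+\tau)\rangle /
(\langle P_1\rangle\langle P_2\rangle)$. An uncorrelated signal gives
$g = 0$; the amplitude $g(0^+)$ of a freely diffusing species equals
$\gamma/N$, the reciprocal apparent molecule number.

Two lag schemes are provided. The *direct* scheme is the brute-force
sum at every integer lag and serves as the reference. The
*multiple-tau* scheme evaluates the same estimator on a quasi-
logarithmic ladder (16 linear lags, then 8 per octave), with one FFT
supplying the raw lag products for traces of any length. A deliberate
design choice: the ladder controls only *which* lags are reported, and
no per-level rebinning of the trace is applied. Classic multiple-tau
correlators average the signal within each level, which biases the
estimate at a nominal lag relative to the plain estimator; computing
exact estimates on the ladder keeps the two schemes numerically
identical at shared lags (they agree to better than $10^{-8}$ relative,
which the test suite enforces) while retaining the logarithmic lag
coverage that diffusion fitting needs. The statistical price — no
intra-level noise averaging — is paid back by fitting across the ~80
ladder points and, optionally, by block-wise standard errors
(`n_blocks`) used as weights.

### Diffusion models

Curves are fitted with the 3D Gaussian-volume diffusion model

$$g(\tau) = b + \Big(1 + \tfrac{T}{1-T}e^{-\tau/\tau_T}\Big)\,
  \frac{\gamma}{N}
  \Big(1+(\tau/\tau_D)^a\Big)^{-1}
  \Big(1+\tfrac{(\tau/\tau_D)^a}{s^2}\Big)^{-1/2},$$

with $s = z/r_0$ the axial-to-lateral beam ratio, $T$ and $\tau_T$ a
triplet (blinking) term, $a$ an anomalous-diffusion exponent (1 for
free diffusion) and $b$ a fitted baseline. A two-component variant
replaces the diffusion factor with a $Y$-weighted sum of two such
terms, with $\tau_{D,1} < \tau_{D,2}$ enforced by convention (the
reported $Y$ is always the fast-component weight). Some published
renderings of this model carry the axial factor to the power $-1$ and a
trailing $+1$ offset, which looks typographically truncated; the
package defaults to the standard form above and exposes
`as_printed = TRUE` to reproduce the literal variant, so either reading
can be tested.

Two conventions that matter for absolute numbers:

* $\gamma$ defaults to 1, i.e. the shape factor is folded into the
  apparent $N$; $2^{-3/2}$ is selectable. Bound-fraction arithmetic
  uses only ratios of amplitudes, where a consistent $\gamma$ cancels.
* Amplitudes $g(0^+)$ are always read from the fitted model, never from
  the noisy first lag bin.

Fits use Levenberg–Marquardt (\pkg{minpack.lm}) with box constraints
enforcing the parameter ranges; non-convergence is flagged in the
result, never silent. The residence time converts to a diffusion
coefficient by $D = r_0^2/(4\tau_D)$ (a factor 2 variant is provided
for the half-waist convention).

### Bound species from FCCS

With $N_g$, $N_r$ the reciprocal autocorrelation amplitudes and
$N_{cc}$ the reciprocal cross-correlation amplitude, the number of
double-labelled molecules is

$$N_{bound} = \frac{N_g\,(N_r + Q\,N_g)}{N_{cc}} - Q\,N_g,$$

where $Q$ is the spectral crosstalk of the green fluorophore into the
red channel. The grouping of this expression is ambiguous as usually
printed; the adopted reading is fixed by the requirement that at
$Q = 0$ it reduce to the textbook relation
$g_{cc}(0) = N_{bound}/(N_g N_r)$ — which it does with $N_{cc}$ defined
as $1/g_{cc}(0^+)$. Whether published "co-movement" percentages are
$N_{bound}/N_g$ or $N_{bound}/N_r$ is often unstated, so both
fractions are reported. A negative corrected bound number (crosstalk
overcorrection) is clipped to zero and flagged.

## The Brownian-dynamics trace generator

`simulate_fcs_trace()` moves point emitters by Gaussian steps of
variance $2D\,\mathrm{d}t$ per axis inside a box with periodic re-entry
(a particle leaving one face re-enters at the opposite one, keeping the
concentration constant — the standard choice for FCS simulation). The
detection profile is the 3D Gaussian
$W = \exp(-2(x^2+y^2)/r_0^2 - 2z^2/z_0^2)$; per-bin counts are Poisson
around the brightness-weighted sum of detection weights plus
background, and the red channel additionally receives a configurable
fraction of the green *molecular* rate (crosstalk). Triplet blinking is
a per-molecule two-state telegraph process with dark fraction $T$ and
correlation time $\tau_T$. The expected occupancy `n_mean` is defined
over the effective volume $V_{\mathrm{eff}} = \pi^{3/2} r_0^2 z$, which
makes the simulated amplitude exactly $g(0^+) = 1/n_\mathrm{mean}$
under the $\gamma = 1$ convention — this identity is derived
analytically and verified statistically in the tests.

Numerical choices:

* **Bin width.** Hardware correlators bin at fractions of a
  microsecond; the correlation shape at lags far above
  $\mathrm{d}t$ is unaffected by the binning, so desk-scale runs use
  1–100 µs for fast species and 0.1–10 ms for slow ones. The
  configuration validator warns when the duration is below 100
  residence times, where correlation estimates become unreliable.
* **Box size.** At least three beam radii per axis (enforced); the
  occupancy in the box follows from `n_mean` by volume scaling.
* **Seeding.** Every generator takes an explicit integer seed; traces
  come from a dedicated `mt19937_64` stream, so identical seeds give
  bit-identical traces and the R session's RNG state is never touched.

### Study protocols at desk scale

The validation suite mirrors the measurement protocols of the system it
emulates, at sizes a desktop handles in minutes:

* **Slow species** (clathrin-like, $D \approx 0.01$ µm²/s): seven
  simulated 200 s traces ("cells") at 1 ms binning, correlation curves
  averaged across cells with `average_curves()` and fitted once. A
  single 200 s trace covers only ~120 residence times and its
  $\tau_D$ estimate scatters by tens of percent — the fluctuations that
  limit FCS of slow species are particle-number fluctuations, which no
  amount of brightness buys back; averaging across cells is how such
  measurements are actually quantified, and brings recovery within a
  few percent.
* **Co-diffusion** (FCCS): a green-only, a red-only and a
  double-labelled species, five molecules each in the volume,
  $D = 1$ µm²/s, 200 s at 0.2 ms binning, five seeds; the planted
  bound number is recovered within 20%.

## FRAP

Recovery traces are normalised affinely so that the fluorescence at the
end of the bleach maps to 0 and the recovered level to 1. "Recovered
level" is by default a plateau estimate — the mean of the final 10% of
samples — rather than the single maximal sample, for robustness to shot
noise; the literal-maximum convention is selectable. The model
$f(t) = A\,(1 - e^{-t/\tau})$ is fitted by least squares. Because the
mobile fraction is only identifiable relative to a total-signal
reference, the reported `mobile_fraction` is $A/\mathrm{pre}$ when a
pre-bleach reference level is supplied and the raw plateau $A$
otherwise; both the amplitude and the converted fraction are kept in
the result, since published mobile fractions do not always state their
convention. When pooling cells, normalised traces are averaged (with
per-point standard errors) *before* fitting.

## TIRF event analysis

The imaging chain is: segmentation image → Laplace enhancement →
threshold segmentation → per-ROI $\Delta F/F$ traces → threshold-crossing
responder selection → classification → ribbon distances.

* **Segmentation image.** The temporal standard deviation of the frames
  inside the classification window. This choice detects positive- and
  negative-going events alike, which a simple difference image would
  not.
* **Laplace enhancement.** A 5-point discrete Laplacian (replicated
  borders) after 1 px Gaussian smoothing, negated so blob centres are
  positive; it suppresses smooth background and sharpens puncta at low
  contrast.
* **Thresholding.** `median + k × MAD` of the enhanced image
  (`k_seg = 6` by default), restricted to an eroded footprint mask
  estimated from the pre-stimulus baseline image. An absolute floor of
  0.1% of the dynamic range keeps noise-free synthetic images from
  segmenting through vanishing Gaussian tails; it is far below any real
  noise level. Components are 8-connected, labelled deterministically
  in raster order, and components below `min_pixels = 4` are dropped.
  Components containing several well-separated intensity maxima (at
  least 3 px apart and above 40% of the component's prominence) are
  split by nearest-maximum assignment, so neighbouring hotspots merged
  by thresholding become separate ROIs.
* **Traces.** $\Delta F/F = (F - F_0)/F_0$ per ROI with $F_0$ the mean
  over a pre-stimulus baseline window (20 frames by default) after
  subtracting a background trace (user mask or the darkest decile of
  pixels). This normalisation makes the whole pipeline exactly
  invariant under global affine intensity rescaling of the movie,
  which the tests verify. ROIs with non-positive baseline are flagged
  and excluded.
* **Responders.** A ROI responds when any post-onset sample exceeds
  $\pm k \times \mathrm{SD}$ of the baseline (default $k = 4$); the SD
  is by default the *average* of per-ROI baseline SDs, with per-ROI SDs
  selectable. Traces are used raw; optional smoothing is left to the
  caller because a fixed smoother would change the effective threshold.
* **Classification.** Responders are classed by the sign of their
  significant excursion within a 10 s window from stimulus onset:
  positive → accumulation, negative → loss. Each event record carries
  the first-crossing onset frame, the signed peak, the
  intensity-weighted centre of mass of its ROI over the response
  window, and a single-exponential recovery constant fitted from the
  trace peak (left unset when the fit fails — the event is kept).

## Ribbon geometry

Ribbon puncta are segmented from the marker channel the same way and
localised by intensity-weighted centre of mass; the effective radius is
that of the equal-area disc. Event-to-ribbon distance is the Euclidean
distance to the nearest punctum centre (ties broken towards the lowest
index). Distance histograms use fixed 0.1 µm bins from zero — wide
enough to be stable at realistic localisation noise, narrow enough to
resolve a ~0.4 µm fusion ring from a ~0.8 µm clathrin-turnover ring.
Pixel coordinates are `[row, col]`; physical positions are micrometres
with the origin at the image corner and pixel centres at half-integer
multiples of the pixel size. All distances are µm, all times seconds.

## Decay kinetics and condition comparisons

Response decays are fitted from the trace peak as
$A e^{-t/\tau}$ or $A(p\,e^{-t/\tau_1} + (1-p)\,e^{-t/\tau_2})$
($\tau_1 < \tau_2$ enforced). `model = "auto"` keeps the double form
only when a nested F-ratio test at $\alpha = 0.05$ says the extra two
parameters earn their keep; a double fit whose constants nearly
coincide (ratio < 1.5) or whose fast fraction pins at 0/1 collapses to
the single fit with a warning. This collapse rule is what keeps the
false-complexity rate at zero on clean single-exponential data.

`compare_conditions()` reports a treated/control ratio of mean fitted
time constants *and* of mean half-recovery times (a "k-fold slowing"
can be read either way), and control/treated event-count folds both as
raw totals and per-terminal means.

## The TIRF movie generator

`simulate_tirf_movie()` builds `baseline + footprint + ribbons +
events + camera noise`:

* an elliptical footprint (bright interior over dark surround) at
  0.1 µm pixels and 0.1 s frame interval — the pixel size is a
  configuration default consistent with high-NA EMCCD imaging, not a
  measured constant;
* static Gaussian ribbon puncta (σ = 0.2 µm, matching a ~200 nm
  effective radius);
* three event classes planted at radial distances from a ribbon drawn
  from $N(0.4, 0.08)$ µm (fusion) or $N(0.8, 0.08)$ µm (accumulation
  and loss), with a minimum mutual separation of 0.35 µm:
  * *fusion*: rises from stimulus onset, peaks ~0.3 s after stimulus
    end, decays as a double exponential (30% at 2.5 s, 70% at 13 s);
  * *accumulation*: onset within one frame of the stimulus, decays
    with a 15 s constant (the 10–20 s range);
  * *loss*: the negative-going mirror of accumulation;
* event peak amplitudes specified in multiples of the baseline noise
  SD (`amp_sd = 8` by default), with the evanescent-field axial decay
  collapsed into the amplitude and an isotropic Gaussian PSF
  (σ = 0.15 µm);
* a camera model `round(gain · Poisson(rate) + N(0, read σ) + offset)`,
  so written movies are integer-valued and TIFF round-trips are exact.

What the generator does **not** emulate — lateral drift, photobleaching,
vesicle motion between frames, pH-dependent reporter photophysics,
EM-gain excess noise, axial PSF structure — bounds what passing tests
mean: they demonstrate that the analysis correctly recovers events of
the modelled kind at the modelled SNR, not that it is robust to every
artefact of real recordings. Ground-truth tables (class, centre, true
ribbon distance, kinetic parameters, seed) round-trip losslessly
through full-precision CSV.

## Validation summary

The test suite checks, among others: exact closed-form values for the
estimators and models on constructed inputs; agreement of the
multiple-tau and direct correlators to $10^{-8}$; recovery of
noiseless generating parameters to $10^{-4}$ relative by every fitting
routine; the simulated amplitude–occupancy identity and count rate
against a Monte-Carlo oracle; stochastic recovery of diffusion times,
bound numbers, FRAP constants and planted imaging events (precision
and recall ≥ 0.95 at 8×SD amplitude, exact class assignment, distance
modes at 0.4 and 0.8 µm); and determinism of every seeded path.
`scripts/acceptance.R` recomputes the package's headline consistency
number (the clathrin diffusion coefficient implied by the
residence-time relation) from scratch on each run.

## Known limitations

* The Brownian simulator treats emitters as points with a single
  diffusion coefficient per species; no photobleaching, saturation or
  detector afterpulsing.
* FRAP fitting covers the reaction-free single-exponential model only;
  diffusion-coupled recovery and bleach-spot geometry corrections are
  out of scope.
* Event detection assumes a stationary footprint; movies with drift
  should be registered upstream.
* Half-recovery-time folds require the caller to supply empirical half
  times; the package does not infer them from fits with undefined
  plateaus.
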