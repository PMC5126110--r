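---
title: "Long-range temporal correlations in EEG amplitude envelopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-range temporal correlations in EEG amplitude envelopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(envlrtc)
```

## The scientific question

Ongoing neuronal oscillations are not memoryless: the amplitude envelope of
a band-filtered EEG signal fluctuates with positive autocorrelations that
decay as a power law and persist over tens of seconds — long-range temporal
correlations (LRTC). Their strength is summarised by the Hurst exponent
\(H\) of the envelope: \(H = 0.5\) for an uncorrelated (random) process,
\(0.5 < H < 1\) for persistent correlations, \(H > 1\) for non-stationarity.
In the criticality framework, LRTC strength tracks the excitation-inhibition
balance of cortical networks, which makes \(H\) a candidate marker for
conditions — insomnia among them — hypothesised to involve altered cortical
excitability. This package implements the full analysis chain for testing
whether \(H\), per electrode and frequency band, differs between an insomnia
disorder (ID) group and controls (CTRL), and how it covaries with the
Insomnia Severity Index (ISI, a 7-item sum score with sub-clinical cutoff 8).

## The estimator: DFA of the Hilbert envelope

For each electrode and each band — theta (4–8 Hz), alpha (8–12 Hz), sigma
(12–15 Hz), beta-1 (15–22 Hz), beta-2 (22–30 Hz) — the signal at 250 Hz is
band-pass filtered with a Hamming-windowed sinc FIR of fixed kernel length
(125, 63, 38, 31, 23 samples respectively), applied in a single pass with
group-delay compensation (`apply_zero_phase()`). Forward–backward filtering
is deliberately avoided: it would double the effective filter order, and the
DFA scale minimum is tied to that order. Filter-length edge transients are
trimmed before envelope statistics.

The amplitude envelope is the modulus of the analytic signal
(`hilbert_envelope()`, FFT construction). Detrended fluctuation analysis
(`estimate_hurst()`) then proceeds as:

1. cumulative sum of the envelope, global linear trend removed
   (`build_profile()`);
2. for each time-scale \(s\): split the profile into non-overlapping
   segments of \(s\) samples (forward from the first sample, trailing
   remainder discarded), remove a local third-order polynomial trend from
   each by least squares, and average the per-segment RMS of the residuals
   (`fluctuation_at_scale()` — mean of per-segment RMS, not RMS of pooled
   residuals);
3. fit an unweighted least-squares line to \(\log_{10} F(s)\) versus
   \(\log_{10} s\) over 20 log-spaced scales; the slope is \(H\).

The scale grid runs from eight times the filter kernel duration (4, 2.02,
1.216, 0.992, 0.736 s for theta…beta-2) up to one eighth of the segment
length (22.5 s for a 180-s segment), so that filter-induced short-range
correlations do not contaminate the fit at the lower end and at least eight
segments support the fluctuation estimate at the upper end. Scales are
floored to integer sample counts; duplicates after rounding are collapsed
with a warning. Two rule ambiguities worth recording: reading "filter
order" as the kernel length in samples reproduces the theta minimum of
4.0 s exactly (125/250 × 8), while the conventional sigma minimum is
sometimes quoted as 1.24 s where the rule gives 1.216 s — a 0.02-s
difference consistent with grid snapping; the rule, not the quoted value,
is implemented.

DFA on exact fractional Gaussian noise recovers \(H\) across 0.55–0.9 with
bias below 0.01 and fit \(R^2 > 0.95\) (see `test-dfa.R`). A caveat that
matters when interpreting surrogate benchmarks: over a 2–22.5 s fitting
range the envelope of band-filtered white noise measures \(H \approx
0.55\), not 0.50. This is not an implementation artifact (the fast
fluctuation code agrees with a naive per-segment polynomial oracle to
1e-10, and DFA of i.i.d. noise gives 0.500): the envelope of a filtered
process is short-range correlated over roughly the filter length, and with
the minimum scale only ~8 times that correlation time the local slopes
have not fully converged to their asymptote. An exact computation —
E\[F²(s)\] from the envelope's measured compact-support autocovariance
via the stationary-increment quadratic form with the cubic-detrend
projection — gives an expected slope of 0.553 over the alpha grid, in
agreement with simulation. Longer recordings (larger maximum scales)
would shrink this positive finite-scale bias; at the 180-s desk scale it
is intrinsic to the stated fitting range, and empirical exponents are
best compared against this realised surrogate baseline rather than the
asymptotic 0.5.

## Group-level inference

Participant-level aggregation uses the grand median of \(H\) across all
electrode × band bins (`grand_median_h()`), and per-band medians across
electrodes (`band_median_h()`). The cohort model is a type-II general
linear model `H ~ group + isi + group:isi` (`glm_type2()`, sums of squares
via `car::Anova`): each main effect is adjusted for the other while
respecting marginality, the appropriate default with unequal group sizes.
Follow-ups are non-parametric: Wilcoxon rank-sum for group differences
(normal approximation with tie and continuity corrections — group sizes
here are 40+, so no exact path is provided) and Spearman correlations with
the \(t\)-approximation \(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n-2\)
degrees of freedom. Per-band association profiles report Spearman
coefficients with 1000-iteration percentile bootstrap confidence
intervals; a correlation is called *robust* when more than 97.5% of
bootstrap replicates share its sign.

Two procedures the source analyses left unspecified are implemented as
explicit, documented choices. The eyes-open/eyes-closed contrast
(`condition_contrast()`) uses paired Wilcoxon signed-rank tests on band
medians, plus a dispersion contrast on each participant's across-electrode
interquartile range — a paired, rank-based reading of "between-participant
variation". The within-versus-across-group comparison
(`within_vs_across_correlation()`) reports within-group and pooled
Spearman coefficients with a bootstrap distribution of their difference;
it is labelled non-canonical since no printed procedure exists to match.

## Spatio-spectral TFCE inference

Per-bin Spearman statistics over the electrode × band lattice are enhanced
with threshold-free cluster enhancement:
\[
t_{\mathrm{tfce}}(b) \;=\; \int_0^{|t_b|} e(h)^{0.66}\, h^{2}\, dh ,
\]
where \(e(h)\) is the size of the connected supra-threshold component
containing bin \(b\). Neighbourhood combines montage adjacency (distance
below a radius) at fixed band with the consecutive-band chain
theta–alpha–sigma–beta-1–beta-2 at fixed electrode. The integral is
discretised with 100 equal increments from 0 to the map's maximum |t|
using the midpoint rule, which converges to the closed-form isolated-bin
value \(t^3/3\) within 0.2% at 100 steps (doubling the steps changes
results by far less than 1%); negative statistics are enhanced
sign-symmetrically. The enhancement kernel is implemented in C++
(union-find per threshold) and is tested for exact agreement with a
brute-force R loop over thresholds using `igraph` components.

Familywise correction uses the max-statistic Monte-Carlo null: each of
1000 permutations shuffles ISI across participants (exchangeable under
the null of no ISI–H association), recomputes the whole map — by
pre-computing standardised ranks, each permutation's map is a single
matrix product — enhances it, and records the maximum \(|t_{\mathrm{tfce}}|\).
Corrected p values use the add-one estimator
\((1 + \#\{\mathrm{null} \ge |t_{\mathrm{tfce}}|\})/(n_{\mathrm{perm}}+1)\),
which cannot return zero. Per-band summaries report the spatial extent
(electrodes with \(p < 0.05\)), marginal electrodes (\(0.05 \le p < 0.1\)),
and the peak bin (minimal p, ties broken by larger \(|t_{\mathrm{tfce}}|\))
with its \(\rho\), \(t\), \(t_{\mathrm{tfce}}\) and \(p\). On 200 null
cohorts the realised familywise error sits within [0.02, 0.08] at nominal
0.05 (see the acceptance tests).

## The synthetic cohort generator

No public recording archive accompanies the analyses this package
implements, so the generator is a first-class module that plants known
structure at three levels.

**Signals.** `generate_fgn()` synthesises exact-covariance fractional
Gaussian noise by circulant embedding — eigenvalues of the embedded
covariance via FFT, so the autocorrelation
\(\rho(k)=\tfrac12(|k+1|^{2H}-2|k|^{2H}+|k-1|^{2H})\) holds exactly at
every lag, with no burn-in. `generate_band_oscillation()` multiplies a
narrowband carrier by the strictly positive envelope \(1 + d\,z\) (depth
\(d\), default 0.5; \(z\) standardised fGn), floored at 0.05 with floor
events counted. Two constructional points deserve emphasis because they
were decisive in validation:

* the fGn modulator is low-pass filtered to \(f_{\mathrm{low}}/2\) before
  use. Raw fGn has most of its variance at frequencies far above any
  physical amplitude envelope; modulating with it spreads the planted
  structure outside the band, where the analysis filter discards it. The
  low-pass leaves the spectrum below the cutoff — hence the DFA fitting
  range, which reads frequencies below ~0.5 Hz — untouched.
* the carrier is white noise filtered to exactly the band with a sharp
  FIR (transition width one tenth of the bandwidth), with its Rayleigh
  amplitude fluctuations compressed by raising the Hilbert envelope to
  the power 0.3. The two extremes both fail: a raw noise carrier's own
  envelope noise (coefficient of variation 0.52) drags recovered
  exponents toward the white-noise floor, while a fully flattened
  (constant-modulus) carrier splatters power across the spectrum through
  phase slips and, by removing all fast envelope noise, leaves the
  modulator's low-pass truncation bias uncompensated at low \(H\).

With this design, planted alpha-band exponents 0.6/0.7/0.8 are recovered
from the direct Hilbert envelope with biases +0.03/−0.00/−0.01 (180 s at
250 Hz, 30 seeds); re-filtering the already narrowband oscillation with
the analysis FIR (as happens inside `compute_h_matrix()` on mixed-band
recordings) adds roughly +0.02 at low H. The narrow sigma band and
the beta bands carry a larger positive bias at low \(H\) (up to ~+0.07)
because their minimum DFA scales sit only a few correlation times above
the carrier's coherence time — a documented limitation, not corrected for.
Amplitude-modulation physics also bounds spectral purity: sidebands extend
a modulator bandwidth beyond the band edges, so while theta and alpha
oscillations hold ≥90% of their power strictly in-band (92% and 90%
measured), the 3-Hz-wide sigma band cannot reach that bound with any
meaningful envelope (~85%), and the beta bands sit at ~88–90%.

**Cohorts.** `generate_cohort_h()` draws ISI uniformly on [8, 28] for 52
ID participants and [0, 7] for 43 CTRL (the inclusion-criteria cutoffs;
the instrument's 7 × 0–4 item structure implies a 0–28 ceiling, and the
sometimes-quoted 0–25 ceiling is not enforced), then plants
\(H = 0.62 + 0.005\,\mathrm{ISI}\) inside group-specific effect masks —
parietal theta for ID, centro-frontal beta-1 for CTRL, six electrodes each
by default — plus independent Gaussian noise (sd 0.02) in every bin,
clipped to (0.5, 1), the range empirically observed for EEG envelopes.
The baseline 0.62, slope and noise were chosen once to give mid-range
exponents and planted associations of roughly \(\rho \approx 0.5\) within
the ID arm — comparable to the peak associations the method is designed to
resolve — and are not revisited. All randomness descends from one master
seed via documented stream labels (`derive_seed()`).

**Recordings.** `generate_cohort_recordings()` sums per-band oscillations
whose planted envelope exponents equal the participant's \(H\) bin values,
plus a 10% broadband noise floor, yielding multichannel recordings that
exercise the entire pipeline; planted exponents are recovered with mean
absolute error below 0.07 end-to-end.

What the generator does *not* emulate: artifacts (ocular, muscular, line
noise), cross-channel and cross-frequency coupling, volume conduction,
1/f background mixtures, and non-stationarity beyond the planted
envelopes. Passing tests therefore demonstrate correctness of the
estimator and inference chain under clean planted structure, not
robustness to real-data contamination — the cleaning stages that would
address the latter are explicitly out of scope.

## Numerical choices and degenerate inputs

* Filters: `signal::fir1` Hamming designs; gain is unity at the passband
  centre; even-length kernels carry an uncompensated half-sample delay.
* Envelope edges: the analytic-signal FFT assumes periodicity, so
  filter-length transients are trimmed at both ends before DFA.
* DFA: non-positive fluctuations (constant envelopes) raise an error
  naming the offending scale rather than returning NaN slopes.
* Constant bins in the correlation map are flagged, zeroed and excluded
  from enhancement with a warning; degenerate bootstrap resamples are
  redrawn and counted.
* Permutation p values can never be zero (add-one estimator); the TFCE
  threshold step is per-map (max |t| / 100), making enhancement
  scale-covariant in t up to discretisation.
* Problem sizes in the test-suite simulations (e.g. 16-electrode grids,
  200 null cohorts at 200 permutations, 20 seeds per planted exponent)
  were chosen as the smallest designs at which the Monte-Carlo error of
  each check is comfortably below its tolerance.

## Reading the outputs

`run_pipeline()` writes per-condition H matrices (long TSV), per-group
TFCE maps (electrode, band, rho, t, t_tfce, p), a JSON report mirroring
the statistics chain (GLM table, follow-ups, band profiles with CIs, TFCE
summaries), and a manifest (package version, seed, sizes, timings). Two
runs with the same configuration and seed differ in no output byte except
the manifest timestamps.
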