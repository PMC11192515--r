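---
title: "Frequency-tagged oddball analysis: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged oddball analysis: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvstag)
```

## The measurement model

Fast periodic visual stimulation (FPVS) presents stimuli at a fixed base rate
$f_{base}$ (6 Hz by default here) while a deviant category recurs at a fixed
subharmonic, the oddball rate $f_{odd} = f_{base}/2$ (3 Hz). Stimulus-locked
neural activity then concentrates at exactly these frequencies: a response at
$f_{base}$ and its harmonics indexes general visual processing, while a
response at $f_{odd}$ (and its harmonics that are *not* multiples of
$f_{base}$) can only arise if the brain discriminates the deviant category
from the standards. The analysis chain is:

1. average the trials of a condition (coherent averaging: phase-locked signal
   survives, noise power shrinks with the trial count);
2. Fourier-transform the average; amplitudes are normalized to $2|X_k|/N$ so
   a bin-aligned sinusoid of amplitude $A$ reads exactly $A$ at its bin;
3. baseline-correct each bin by subtracting the mean of its surrounding bins
   (the local noise-floor estimate);
4. the *discrimination response* is the baseline-corrected amplitude at
   $f_{odd}$, compared between the alternating (experimental) and uniform
   (baseline) sequence types.

Group inference uses a paired, one-tailed cluster-based permutation test on a
sensor (or vertex) adjacency graph, Hedges $g$ for effect size, and JZS Bayes
factors where the frequentist test is inconclusive.

## Epoch geometry and bin alignment

The single-bin response definition only works if the tagged frequencies fall
*exactly* on FFT bins. An epoch of $n_{cycles}$ base cycles lasts
$n_{cycles}/f_{base}$ seconds (160 cycles at 6 Hz: $26.6\overline{6}$ s,
conventionally printed as 26.7 s), which puts $f_{base}$ and $f_{odd}$ on
integer bin indices regardless of sampling rate. The frequency resolution is
the reciprocal trial duration, $0.0375$ Hz.

Two sampling-rate constraints follow:

- `fs * n_cycles / f_base` must be an integer sample count. The package
  default is `fs = 600` Hz (16000 samples per epoch); rates like 1000 Hz are
  rejected with an explicit error because $1000 \cdot 160/6$ is not an
  integer and the resulting leakage would silently break the single-bin
  response definition.
- A decimated rate must keep the epoch an integer number of samples: 250 Hz
  is incompatible with an $80/3$ s epoch, so the pipeline's natural decimated
  rate is 300 Hz. `filter_and_downsample()` accepts any integer decimation
  factor.

`extract_response()` refuses targets farther than half a bin from the nearest
bin and refuses bins whose correction window crossed the spectrum edge, so a
misconfigured analysis fails loudly rather than shifting the target.

## The synthetic generator

No raw recordings ship with the package; every stage is instead exercised on
a generator whose statistical structure matches what the analysis assumes:

- **Signal.** Sinusoids at base harmonics (default amplitudes 1 and 0.4 at 6
  and 12 Hz) in every condition; sinusoids at non-coinciding oddball
  harmonics (default amplitude 0.5 at 3 Hz) only in experimental sequences.
  Oddball harmonics that coincide with base harmonics are dropped with a
  warning, since they carry no discrimination information.
- **Topographies.** Unit-peak Gaussian falloff over great-circle distance
  from a configurable center direction, with separate centers for the base
  and oddball responses (defaults: posterior-midline and left-lateralized
  posterior, widths 0.06 and 0.05 m). Spatially smooth effects are what the
  cluster test's adjacency assumption is built for.
- **Noise.** Gaussian $1/f^\beta$ noise ($\beta = 1$, the canonical resting
  MEG shape) generated by frequency-domain shaping, with exact time-domain
  standard deviation `noise_sigma` (default 1, in the same arbitrary field
  units as the signal amplitudes; at these defaults a 6-trial average gives a
  single-subject oddball response roughly 25 standard errors above the
  per-bin noise floor at the topography peak, comfortably in the regime of a
  strong frequency-tagging response).
- **Phases** are drawn once per run (`phase_seed`) and shared across trials
  and subjects, so coherent averaging preserves the signal; amplitude spectra
  are phase-invariant, so this costs no generality.
- **Subjects** scale all signal amplitudes by $\max(0.05,\; 1 + CV \cdot z_s)$
  with `subject_cv = 0.2` by default; the manifest records every drawn value.
- **Layout.** 102 sites quasi-uniformly placed (Fibonacci lattice) on a
  0.09 m hemisphere, each with one magnetometer and one orthogonal planar
  gradiometer pair, mimicking a 306-channel whole-head system.

The default cohort shape is 21 subjects and 6 trials per condition and
sequence type, with five named contrasts (alphabetic, readability,
familiarity, meaningfulness, lexicality) represented purely as
(condition, baseline) label pairs with configurable oddball gains — no
linguistic content is simulated. The default gains (1, 0.25, 0.25, 0, 0.75)
make the first and last contrasts strong, the middle ones weak or null,
mirroring a hierarchy from clearly detectable to absent effects.

What the generator does **not** emulate: forward-modelled source-to-sensor
physics (topographies are imposed, not projected), sensor-kind-specific units
(fields are unitless; `kind` only matters for planar pair combination),
artifacts, non-stationarities, or contrast-response nonlinearities. Passing
tests therefore validate the *analysis chain* under its own assumptions, not
the behavior of the chain on real MEG.

A practical note on cost: because the signal is identical across trials of a
run and the noise is Gaussian, the average of $T$ trials equals signal plus
$1/f^\beta$ noise of scale $\sigma/\sqrt{T}$. `simulate_trial_average()`
draws that average directly — distributionally exact and $T$ times cheaper —
and `run_experiment()` uses it, streaming one subject-condition at a time so
the full 306-sensor cohort never resides in memory. `simulate_cohort()`
retains the explicit per-trial API.

## The baseline correction

The correction subtracts, from each bin, the mean of 20 surrounding bins: 10
per side, skipping the immediately adjacent bin on each side and dropping the
single largest and single smallest of the pooled 22 candidates. All three
counts are configurable (`baseline_config()`); the alternative reading of the
convention — a fixed 10-bin window per side with exclusions taken *inside*
it — is one configuration away (`n_used_per_side = 8`-ish variants). Edge
bins without a full symmetric window are marked undefined rather than
corrected asymmetrically; the 3 Hz target sits 80 bins from the edge at the
default resolution, far from the issue.

Two estimator properties worth knowing:

- **Local flatness matters.** The window spans ±12 bins (±0.45 Hz at the
  trial-length resolution). On a locally flat noise floor the corrected value
  at a signal-free bin is unbiased to well within Monte Carlo error; at much
  coarser resolutions the same window sees the curvature of the $1/f$ floor
  and inherits a small bias. This is a property of the estimator itself, not
  of the implementation.
- **Noise-floor subtraction bias.** At a bin carrying a strong coherent
  signal $A$, the measured magnitude is $|A + Z| \approx A$ for $A \gg
  \sigma_{bin}$ — the noise floor does not add coherently — while the
  correction subtracts the *full* floor (mean Rayleigh amplitude of the
  neighbours). The corrected amplitude therefore underestimates $A$ by
  roughly the floor height: about 4% at the default SNR (6-trial averages).
  The bias is identical in both conditions' noise contributions and far
  smaller than between-subject variability, so group contrasts are
  unaffected; absolute amplitude recovery is validated against replicate
  subjects drawn under the full variability model, where the replicate mean
  sits well within three standard errors of the injected value.

## Cluster-based permutation inference

Node-wise paired $t$ statistics (experimental minus baseline per subject) are
thresholded at the one-tailed critical value at `cluster_forming_alpha`
(default 0.05, df $= n - 1$ — the field's standard default; the threshold is
exposed in the configuration). Suprathreshold nodes are grouped into
connected components of the adjacency graph, each scored by its mass (sum of
member $t$ values; cluster size is available as an alternative statistic).
The null distribution of the *maximum* cluster mass is built by randomly
flipping each subject's difference map sign — the exact exchangeability
scheme of a paired design under the null — and each observed cluster gets
$p = (1 + \#\{null \ge mass\}) / (1 + n_{perm})$, which cannot reach zero.
When `n_permutations` is at least $2^n$, the engine switches to exhaustive
enumeration of all sign assignments and reports exact permutation p values
($\#\{null \ge mass\}/2^n$, floored at $1/2^n$ by the identity assignment);
`exhaustive_signflip_test()` exposes the same enumeration directly and serves
as the Monte Carlo engine's oracle in the tests.

Zero-variance nodes (possible in degenerate synthetic data, impossible in
noisy recordings) have no defined $t$ and are excluded from clustering with a
warning. Reported cluster masses are permutation statistics and are never
interpreted as $t$-distribution quantiles.

Adjacency is a plain distance threshold within one sensor kind at a time
(planar pairs are combined by root-sum-of-squares first and live at their
site position). The threshold is a free parameter: a 6 mm neighbourhood is
the right scale for dense source grids (thousands of vertices a few
millimeters apart), while the default synthetic helmet has ~25 mm site
spacing, so `experiment_config()` defaults to 35 mm for sensor-level graphs.

## Effect sizes and Bayes factors

Hedges $g$ for the paired contrast is $\bar d / s_d$ times the small-sample
correction $J(\nu) = 1 - 3/(4\nu - 1)$. The default 95% CI inverts the
noncentral $t$ distribution of the one-sample statistic; a seeded percentile
bootstrap (10,000 resamples) is available as an alternative, since no single
CI convention dominates the literature.

The JZS Bayes factor for a paired design places a Cauchy prior of scale $r =
0.707$ on the standardized effect and integrates the $g$-prior marginal
likelihood by adaptive quadrature in log space (verified against dense
trapezoid integration to $10^{-6}$ relative error and against an independent
implementation). $BF_{10} < 1/3$ counts as moderate evidence for the null,
$BF_{10} > 3$ for the alternative; exact boundary values are classified
inconclusive, matching the strict inequalities of the evidence-table
convention. Per-ROI tabulation reports vertex counts and integer-rounded
percentages in each class. The default ROI labelling of the synthetic helmet
is its four quadrants (left/right × anterior/posterior); any named node → ROI
map can be supplied.

## Numerical and scale choices

- Spectrum normalization $2|X_k|/N$ makes simulator amplitudes directly
  readable off the spectrum; the DC bin is not doubled.
- The band-pass stage is a zero-phase (forward–backward) Butterworth cascade:
  order-2 high-pass at 0.1 Hz, order-10 low-pass at 100 Hz. The low-pass
  order is chosen so a 120 Hz tone is attenuated below 5% after the
  forward–backward pass; it doubles as the anti-alias filter for integer
  decimation. `run_experiment()` skips this stage by default: synthetic
  epochs contain no out-of-band energy, and skipping keeps the tagged bins
  exactly aligned at the simulation rate.
- Monte Carlo p values use the +1 correction; exhaustive p values do not need
  it (the identity assignment is part of the enumeration).
- All randomness flows from explicit integer seeds through a splitmix-style
  stage-seed derivation; `run_experiment()` writes a manifest (stage seeds,
  config and output checksums) and re-running a config reproduces every
  output file byte-identically.
- Test and validation problem sizes are deliberately desk-scale: property
  checks use 12–24-site helmets, 40-cycle epochs at 300 Hz, 8–12 subjects,
  and 200–500 permutations; the family-wise error calibration uses 500
  null simulations. The defaults of `sim_config()` and `experiment_config()`
  remain the full study shape (306 sensors, 160 cycles, 21 subjects, five
  contrasts, 5000 permutations).

## Known limitations

- Absolute response amplitudes inherit the ~4% noise-floor subtraction bias
  described above; contrasts do not.
- The spectral stage analyzes the oddball fundamental only; harmonic
  summation across oddball harmonics is out of scope.
- Graphs are supplied or built from coordinates; the package performs no
  source reconstruction, so "vertex-level" analyses are generic graph
  analyses.
- The misalignment guard in `extract_response()` cannot trigger for an
  in-range target on a uniform bin grid (every frequency is within half a bin
  of some bin); it protects against out-of-range targets and undefined edge
  bins, and documents the bin-alignment contract at the call site.
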