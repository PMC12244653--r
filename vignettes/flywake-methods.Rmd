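---
title: "Methods: feature-based classification of conscious state in fly LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature-based classification of conscious state in fly LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywake)
```

## Overview

`flywake` implements an end-to-end analysis for asking which univariate
time-series features of fly local field potentials (LFPs) discriminate
wakefulness from anesthesia or sleep, and whether they keep working on flies
and datasets they were not trained on. The pipeline is: simulate (or load) a
multi-fly, multi-dataset epoch collection; preprocess (bipolar
re-referencing, epoch mean subtraction, line-noise removal); extract a
registry of named features per epoch and channel; train per-(feature,
channel) nearest-median classifiers on a discovery cohort; evaluate by
leave-one-fly-out cross-validation and on independent datasets, raw and
batch-normalized; compute the within-fly effect-direction consistency
statistic; test everything against permutation nulls with per-channel FDR
control; and summarize with cross-dataset significance counts and
correlation-distance feature clustering.

## The synthetic study generator

### Signal model

Each bipolar channel signal is a stationary first-order autoregressive
process (an AR(1), the discretized Ornstein–Uhlenbeck process):
$x_t = \varphi\, x_{t-1} + \varepsilon_t$ with
$\varphi = \exp(-\Delta t / \tau)$, $\Delta t = 1000 / f_s$ ms, and
innovation SD $\sigma\sqrt{1 - \varphi^2}$ so the stationary SD is exactly
$\sigma$. This is the simplest process with a tunable autocorrelation
timescale: its lag-$k$ autocorrelation is $\varphi^k$, so
$\tau = 30$ ms at 1000 Hz puts the lag-30 autocorrelation at
$e^{-1} \approx 0.368$. Wake-like epochs default to $\tau = 30$ ms and
$\sigma = 1.5$; unconscious-like epochs to $\tau = 8$ ms and $\sigma = 1$,
encoding the two robust condition effects the pipeline is meant to recover:
a slower autocorrelation timescale and a larger signal variance during
wakefulness. The variance ratio is a free parameter (only its direction is
constrained by the phenomenon being emulated); 1.5 is a deliberately
moderate choice so that amplitude features are separable but not trivially
so.

### From channels to electrodes

The analysis consumes *electrode* recordings and derives channels by
adjacent-electrode subtraction, so the generator must produce electrodes
whose differences carry controlled per-channel effects. It builds electrode
$i$ as a partial sum of independent latent channel processes plus a shared
reference process: $e_i = r + \sum_{j \ge i} c_j$. Bipolar re-referencing
then returns exactly $e_i - e_{i+1} = c_i$, giving precise per-channel
control: the wake-condition parameters at channel $j$ are
$\text{unconscious} + p_j \cdot (\text{wake} - \text{unconscious})$ where
$p_j$ is the channel effect profile ($p_j = 0$ makes the two conditions
statistically identical at that channel, the basis of the false-positive
calibration tests). The default profile decays linearly from 1 at the
deepest channel to 0.25 at the shallowest, mimicking effects concentrated in
central brain structures. A deliberate artifact of this construction is that
deeper electrodes have larger raw variance; it is invisible after
re-referencing, which is the only path the analysis uses.

### Nuisance structure

- **Per-fly baseline**: one additive offset per fly,
  $\mathcal{N}(0, \texttt{fly\_offset\_sd}^2)$, constant across that fly's
  epochs, conditions and electrodes. It is removed by epoch mean
  subtraction, as a voltage baseline should be.
- **Batch effects** per dataset: a multiplicative gain, an additive voltage
  offset, and an optional 4th-order Butterworth low-pass (applied with
  zero-phase filtering via the `signal` package), emulating a cohort
  recorded through different hardware. The gain is the interesting one for
  the analysis: it shifts the values of amplitude-family features
  (SD, rms, Poincaré SDs, band powers) in the evaluation set, which defeats
  discovery-trained thresholds until batch normalization restores them —
  the generalization failure mode the pipeline's raw-versus-normalized
  contrast is designed to expose. The low-pass cutoff is a free parameter
  with no default (none applied unless configured).
- **Line noise**: a mains sinusoid (default 50 Hz — a configuration value,
  since recordings may come from either mains standard) added to each
  electrode epoch with amplitude `line_noise_amp` (default 0.5) and an
  independent random phase per (epoch, electrode). Independent phases are
  essential: a perfectly common-mode sinusoid would be cancelled by bipolar
  subtraction and the line-noise remover would never be exercised
  downstream.

### Determinism

Every fly consumes an independent random stream whose seed is derived
arithmetically from the master seed and the fly's global index. Identical
configurations therefore give byte-identical studies, and appending flies or
datasets never perturbs existing ones — a property the tests assert
directly.

### What the generator does not emulate

Real fly LFP is neither Gaussian nor spectrally AR(1)-shaped; it has
oscillatory structure, nonstationarity within epochs, movement and stimulus
artifacts, and cross-channel correlations beyond the shared reference.
Passing the parameter-recovery tests therefore demonstrates that the
*pipeline* is correct and calibrated — that real effects of the modeled kind
are detected and null channels are not — not that any particular feature
would win on real recordings.

## Preprocessing conventions

Order of operations: re-reference, subtract each epoch's mean, then remove
line noise per epoch and channel. Subtraction direction is deeper minus
shallower (channel 1 = deepest pair); the choice only flips feature signs,
which the classifier learns from data anyway. Epoching takes consecutive
non-overlapping windows from the first sample and discards any sub-epoch
remainder (a 20 s chunk yields eight 2.25 s epochs, dropping 2 s).

The line-noise remover fits a sinusoid at the mains frequency by least
squares on sine, cosine and intercept regressors and subtracts the fit. The
multitaper parameters carried by `preprocess_params` (9 tapers,
time-bandwidth 5, padding factor 2) describe the reference multitaper
F-test estimator this remover stands in for and are reserved for such
variants; the regression fit meets the operative contract — at least 20 dB
attenuation of an injected mains sinusoid with under 5% RMS distortion of
uncontaminated signal — which the acceptance tests measure directly. The
intercept keeps cleaned epochs exactly zero-mean even though 2.25 s spans a
non-integer number (112.5) of 50 Hz cycles. A periodogram-based check
(`line_noise_excess_db`) stands in for visual power-spectrum inspection:
after cleaning, power at the mains frequency must sit within 6 dB of the
neighboring-frequency median.

## Feature conventions

All SDs use the $N-1$ denominator; autocorrelations use the biased
normalization (sum over $N-k$ lagged products divided by the full-sample sum
of squares), the standard choice that stabilizes high lags. Standardized
moments divide the $1/N$ central moment by $\mathrm{SD}^k$, so order 4 is
ordinary (non-excess) kurtosis, 3 for a Gaussian. Lags are in samples, so at
1000 Hz `AC_30` probes the 30 ms timescale.

Worth calling out:

- **Welch PSD**: rectangular window, segment length
  $\min(N, 1024)$, 50% overlap — fixed defaults. Band areas integrate the
  one-sided PSD over equal divisions of $[0, \mathrm{Nyquist}]$; edge
  frequency at $P$% is the lowest frequency where the cumulative PSD reaches
  $P$% of total power.
- **Entropies**: sample entropy excludes self-matches, approximate entropy
  includes them ($m = 2$, $r = 0.2\,\mathrm{SD}$, Chebyshev distance);
  permutation entropy uses ordinal patterns of 3 consecutive samples,
  normalized by $\log_2 3!$; Lempel–Ziv complexity binarizes at the median,
  counts LZ76 phrases by exhaustive-history parsing, and normalizes by
  $\log_2(N)/N$. On constant input, sample/approximate entropy return
  missing; permutation entropy and LZ return 0 by convention.
- **Correlation dimension** (`NL_BoxCorrDim_50_ac_5_minr13`): delay
  embedding with delay at the first zero crossing of the ACF, dimension 5,
  correlation sums over 50 log-spaced radii, reporting the local slope of
  $\log C$ vs $\log r$ at scale index 13. The scale index is a parameter
  because the hctsa-internal semantics of the identifier suffix are not
  fully documented; the interpretation here (a fixed position on the radius
  grid) is one reasoned reconstruction.
- **Finite-sample bias**: the per-epoch lag-30 autocorrelation of a
  $\tau = 30$ ms AR(1) at $N = 2250$ averages about 0.035 below the
  theoretical $e^{-1}$, the familiar negative bias from estimating the mean
  and normalizing within epoch. Tests compare against the closed form with
  a band that accommodates this bias.

A feature is *invalid* at a channel if, across all discovery epochs there,
it returns only missing values or a single constant value; invalid features
are dropped from training, testing, and FDR families. Infinities are kept:
they order correctly through medians and thresholds. The outlier-robust
sigmoid scaling (for visualization) maps values through
$1/(1 + \exp(-(v - m)/(1.35\,q)))$ with reference median $m$ and IQR $q$,
then min-max rescales by the reference's transformed range; evaluation
values always use discovery scaling parameters, and out-of-range values
saturate at the bounds.

## Classification and inference conventions

- **Ties**: a value exactly on the threshold is classified unconscious
  (deterministic, measure-zero for continuous features). Equal class
  medians are flagged degenerate; the classifier's direction defaults to +1
  there, while the effect-direction *label* follows the literal rule
  "+1 if the wake median is greater, −1 otherwise". Missing test values
  cannot be classified and count as errors.
- **Permutation null for accuracy**: labeling each of $n$ epochs
  independently with probability $1/2$ makes null accuracy exactly
  $\mathrm{Binomial}(n, 1/2)/n$; the implementation draws binomial counts
  directly rather than materializing label vectors. 7,702 repetitions by
  default (one per candidate feature in the full reference library).
  P-values use the add-one rule $(1 + \#\{\text{null} \ge \text{obs}\}) /
  (N + 1)$, which avoids $p = 0$ and converges to the empirical quantile.
- **FDR**: Benjamini–Hochberg step-up at $q = 0.05$ within each channel
  (and, for evaluation tables, within each dataset × condition pair ×
  normalization). BH rather than BY because the dependency among related
  features (e.g. neighboring autocorrelation lags) is positive, under which
  BH controls FDR.
- **Batch normalization**: per (feature, channel), z-score with the
  evaluation dataset's own mean/SD over all its epochs and back-transform
  with the discovery mean/SD; infinities are ignored in the moments and
  pass through unchanged; zero evaluation SD yields missing.
- **Consistency**: strictly-below counting (ties count as not-below,
  configurable only by preprocessing the values); flies weighted by their
  wake-epoch counts, with equal-fly weighting as an option. Its permutation
  null draws each wake epoch's below-proportion uniformly from the
  achievable discrete set $\{0, 1/n_u, \dots, 1\}$ — the discrete reading
  of "assigning the portion with equal probability" — rather than a
  continuous uniform; for a single fly with one epoch per condition the
  null is honestly two-point on $\{0, 1\}$.
- **Clustering**: distance $1 - |\rho_\mathrm{Spearman}|$ with
  pairwise-complete observations, average linkage (the method is
  configurable; average is a standard default when none is dictated), flat
  groups cut at 0.7. Features with fewer than 10 complete pairs are
  excluded.

## Problem sizes used in the test suite

The validation study mirrors the reference design at reduced width: 13
discovery plus 12 evaluation flies, 8 epochs per condition of 2.25 s at
1000 Hz, but 5 electrodes (4 bipolar channels, effect profile 1, 0.75, 0.5,
0 — the zero-effect channel drives the false-positive calibration check)
and the fast feature subset (excluding the $O(N^2)$-per-epoch sample /
approximate entropy and correlation dimension, which are unit-tested
separately). These sizes are the package's validation choices: they keep
the whole suite in the tens of seconds while leaving every statistical
assertion well-powered. The evaluation dataset carries a 3× gain shift, so
the suite asserts the full qualitative pattern: timescale features
generalize raw, amplitude features only after normalization, both
significant in discovery, and the zero-effect channel's FDR fraction stays
near $q$.

## Known limitations

- The feature registry is a curated ~24-feature subset of the thousands in
  a full highly-comparative library; registry entries are easy to add via
  `feature_def()`, but no claim is made that the subset spans all feature
  families equally.
- The generator's AR(1) spectrum cannot distinguish features that would
  disagree only on richer dynamics (oscillations, bursts, nonstationarity).
- The least-squares line-noise remover assumes a stable mains frequency
  within an epoch; it does not track drifting line components the way an
  F-test-per-taper method can.
- `hctsa` bit-equivalence is explicitly not a goal; names are kept for
  traceability, semantics are defined by this package's documented formulas.
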