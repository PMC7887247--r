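---
title: "Pairwise maximum entropy models of iEEG power states and their structural substrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise maximum entropy models of iEEG power states and their structural substrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfc)
```

## The scientific problem

Multichannel intracranial EEG (iEEG) shows rich correlated fluctuations of
band-limited power across electrodes. A model-free correlation between two
channels cannot distinguish a direct interaction from an indirect path or a
shared input. The pairwise maximum entropy model (MEM) — the Ising model of
statistical physics — addresses this: it is the *least-structured* probability
distribution over binary channel states that reproduces the observed
activation rates and pairwise co-activation rates. Its interaction matrix
`J` therefore separates direct from mediated coupling, and the central
scientific question this package operationalizes is whether those inferred
interactions track the white-matter structural connectome (streamline counts
between the regions under the electrodes) beyond what inter-electrode
distance alone predicts.

`memfc` implements the full chain: raw multichannel recordings are converted
to binarized band-power states; a pairwise MEM is fitted by pseudo-likelihood
(or exactly, for small systems); the fitted interactions are compared against
structural connectivity with correlation and ROC analysis; and significance
is assessed against a distance-preserving geometric resampling null, with
conventional functional-connectivity estimators (Pearson, partial
correlation, PLV, PLI, WPLI) as comparison methods.

## From signal to binary states

1. **Montage.** iEEG is a relative measure, so three re-referencing schemes
   are supported: `referential` (identity), `global` (each channel's
   least-squares regression residual on the across-channel mean, removing
   reference noise), and `local` (the residual of a multiple regression on
   the four nearest channels, suppressing volume conduction). Global
   regression is idempotent; the implementation guards the degenerate second
   pass where the residual mean signal is numerically zero.
2. **Band power.** The signal is cut into non-overlapping 100-s segments and
   decomposed with an analytic Morlet wavelet (centre parameter 6,
   log-spaced frequencies, 6 voices per octave) computed by FFT convolution
   with reflection padding; power is averaged across the frequencies inside
   each band and segments are concatenated. The wavelet is
   amplitude-normalized (unit peak in frequency), so a unit-amplitude
   sinusoid produces the same envelope at any frequency.
3. **Binarization.** Each band-power series is demeaned, high-pass filtered
   at 0.5 Hz (zero-phase 4th-order Butterworth) to strip ultra-slow drift,
   z-scored over the whole series, thresholded (`z > 0` or `z > 1`; ties at
   the threshold count as off, a measure-zero event fixed for determinism),
   and decimated by 10 to reduce temporal dependence. Demeaning before the
   filter makes the states exactly invariant to affine transforms of power.
4. **Electrode selection.** Where several electrodes share an atlas region,
   only the one closest to the region centroid is kept, giving one channel
   per sampled region.

Band edges default to conventional values (theta 4–8, alpha 8–13, beta
13–30, gamma 30–80, high gamma 80–180 Hz) and are fully configurable, since
only the 4–180 Hz span and the band names are fixed by convention. Whether
z-scoring should be per segment or over the concatenated record is a genuine
design choice; the package z-scores over the concatenated record, which keeps
slow between-segment power differences informative.

## The model and its fitters

For binary states $\sigma \in \{0,1\}^N$ the model is
$P(V) = e^{-E(V)}/Z$ with
$E(V) = -\sum_i h_i\sigma_i - \tfrac12\sum_{ij} J_{ij}\sigma_i\sigma_j$.
`h` is a channel's intrinsic activation tendency; `J` the pairwise
interaction. The equivalent $\{-1,+1\}$ parameterization is related by
$J = 4\tilde J$, $h_i = 2\tilde h_i - 2\sum_j \tilde J_{ij}$, and
`convert_convention()` maps between them with state probabilities preserved
to machine precision (this is tested by enumeration).

Two fitters are provided:

* `fit_exact_gradient()` (N ≤ 15) matches moments against the exactly
  enumerated distribution. The problem is concave, so plain gradient ascent
  with an adaptive step converges to the unique optimum; convergence is
  declared when the largest absolute moment mismatch falls below `tol`
  (default 1e-4).
* `fit_pseudolikelihood()` maximizes the product of single-channel
  conditional likelihoods, avoiding the partition function. It runs in the
  $\{-1,+1\}$ convention with full-batch tanh-form model moments and the
  gradient updates $h_i \mathrel{+}= \epsilon(\langle\sigma_i\rangle_{emp} -
  \langle\sigma_i\rangle_{model})$ and likewise for $J$. The estimator
  converges to maximum likelihood as $T \to \infty$. Because fitting each
  channel's row independently would break the symmetry of `J`, the gradient
  is symmetrized each step — this has the same fixed points as symmetrizing
  `(J + t(J))/2` once after convergence but keeps the iterate symmetric
  throughout. Initialization is `h = 0, J = 0`; the learning rate starts at
  0.05, grows geometrically (×1.02 per improving step, capped at 40× the
  initial value) and backs off (×0.7) when the moment error oscillates.
  These optimizer constants are implementation choices, not scientific
  parameters: the optimum is defined by the moment-matching condition alone.
  The per-iteration $O(TN^2)$ work is done in compiled code.

Non-convergence is never silent: the fit carries diagnostics
(`glance()`) and a warning is raised.

### Partition function from the silent state

In the zero-one convention the all-off state has energy exactly zero, so
$p(\text{silent}) = 1/Z$. `estimate_state_probabilities()` exploits this:
the model probability of any observed state is
$e^{-E(x)} \times p_{emp}(\text{silent})$, requiring the silent state to be
observed at least once (an explicit error otherwise — no pseudo-counts are
injected, because an unobserved silent state means the anchor is simply not
measurable at that threshold). Goodness of fit uses the modified divergence
$D(P,Q)=\sum_x P(x)\,|\log_2 P(x)/Q(x)|$; the absolute value penalizes
overestimated states, which matters precisely because the anchored model
probabilities are not normalized.

## Comparison estimators

Co-activation rates (raw $\langle\sigma_i\sigma_j\rangle$ and Pearson
correlations of the binary series — both are offered because the two
readings differ in whether base rates are retained), Pearson correlation of
power series, residual-regression partial correlation (segment-wise on
hour-long windows, decimated by 10, averaged; it agrees with the
inverse-covariance formula $-p_{ij}/\sqrt{p_{ii}p_{jj}}$ on well-conditioned
data, which the tests verify to 1e-6, and falls back to a small ridge on
rank-deficient regressors), and the phase-synchrony family from
Hilbert-transformed band-passed signals: PLV $|E\{e^{i\theta}\}|$, PLI
$|E\{\mathrm{sgn}\,\Im X\}|$ and WPLI $|E\{\Im X\}|/E\{|\Im X|\}$ with
$X = Z_1 Z_2^*$. Expectations are time averages of the per-sample analytic
cross-spectrum, taken per hour-long segment and then averaged — matching the
PLV pipeline; `sgn(0) = 0`, so exact zero-lag pairs score PLI 0, and an
identically zero imaginary cross-spectrum makes WPLI degenerate (flagged 0).

## The geometric structural null

Streamline counts fall off steeply with distance and iEEG electrodes sample
cortex in tight patches, so distance alone predicts structural connectivity
almost perfectly. The geometric null controls for this: atlas regions are
resampled so that the null set reproduces the *pairwise distance profile* of
the recorded regions. The algorithm seeds with a random atlas pair drawn
from the 5% of pairs whose distance best matches the empirical
maximum-distance pair, then greedily (no backtracking) adds the
(empirical region, unused atlas region) pair minimizing the L1 mismatch of
distances to all previously matched regions. The exact matching cost of the
original procedure lives in supplementary pseudocode not reproduced in the
main text; the L1 rule is this package's documented stand-in, chosen for
robustness to single large mismatches. Because the seed pair's orientation
is undetermined at step one, both orientations are run and the one with the
smaller mean distance error is kept, which also makes the null recover an
exact translated copy of the empirical configuration when one exists (a
test). Null candidates may include the recorded regions themselves.

On a 600-region synthetic atlas with 128 grid electrodes, 100 seeded nulls
show a mean per-region distance error of about 5 mm — smaller than the mean
electrode-to-region-centroid offset (~8 mm) of the same synthetic patient,
so the null's geometric error is within the tolerance already accepted when
assigning electrodes to regions — and their pairwise-distance distributions
pass a KS comparison against the empirical one in ≥95% of seeds.

Coupling statistics are then one-sided permutation tests:
$p = (1 + \#\{null \ge obs\})/(1 + n_{null})$ (add-one, so $p$ is never 0),
with Benjamini–Hochberg FDR correction across frequency bands.

## The synthetic cohort: what it emulates and what it does not

Every stage is testable without patient data through a generator with
planted ground truth:

* **Geometry** — atlas centroids uniform in a 140 × 120 × 100 mm box;
  electrodes as 1–3 rectangular grid patches at 10 mm pitch with 0.5 mm
  jitter, each assigned to its nearest atlas region. This mimics subdural
  grid/strip coverage without an anatomy dependency.
* **Structure** — edge existence and mean streamline count decay
  exponentially with distance (default decay 30 mm, density 0.3, peak count
  1000) with Poisson dispersion; no generative connectome model is claimed,
  only the distance-decay and dispersion features the analysis depends on.
* **Planted model** — `J` proportional to the unit-max log-normalized
  streamline counts between occupied regions plus symmetric Gaussian noise
  (sd 0.02); `h` calibrated by damped per-unit log-odds corrections from
  short Metropolis runs so the mean activation rate hits its target
  (default 0.3). The default coupling scale of 0.5 keeps the network in the
  paramagnetic regime — at scales near 1 the planted network crosses a
  ferromagnetic transition and strongly coupled units saturate, making the
  target rate unattainable for any `h`.
* **Forward signal model** — a test harness, not a physiological claim:
  each channel is a band-limited oscillatory carrier whose envelope is 1
  when 'on' and 0.2 when 'off' (smoothed over 50 ms), plus 1/f pink noise, a
  shared reference signal, and distance-weighted shared local sources. The
  carrier mixes a random-phase tone at the band's geometric-mean frequency
  with 25% band-limited Gaussian noise: a purely stochastic narrowband
  carrier has a Rayleigh-like envelope whose within-state fluctuation masks
  the planted modulation (round-trip state recovery saturates near 73% even
  without added noise), whereas the mostly coherent carrier keeps the
  harness informative (>80% recovery at moderate noise, 0.15 amplitude per
  source). Planted states switch every 0.25 s by default so their spectrum
  sits mostly above the 0.5 Hz power high-pass — slower planted states are
  destroyed by the analysis pipeline's own filter, which is a property of
  the method, not a bug in the harness.

Passing tests on this cohort show the *inference chain* is correct under a
model whose assumptions (static states, stationary carriers, exponential
distance decay, no artifacts, no epileptiform activity) are idealized. They
do not show that real iEEG satisfies those assumptions; with real data the
non-stationarity of power, artifacts, and tractography errors all enter.

## Problem sizes and numerical choices

The test-suite and acceptance-script problem sizes are desk-scale choices:
N = 10 units and T = 1e5 exact samples for parameter recovery; N = 3 and
1e5 kept sweeps for sampler validation; a 600-region atlas with ~70 occupied
regions and 100 seeded nulls for null fidelity; ~50-region patients with
T = 2e4 Metropolis samples and 200 nulls for the end-to-end detection
property; 20 sparse-structure patients (15 mm decay) at T = 3e4 for the
kurtosis contrast. Degenerate inputs are handled explicitly: constant
channels error in binarization and warn (with moment clipping at
±(1 − 1/2T)) in fitting; empty null streamline submatrices are excluded
from permutation distributions; ROC requires both classes; ties in ROC
weights advance the curve diagonally so the AUC equals the Mann–Whitney
rank statistic exactly.

## Known limitations

* The pseudo-likelihood fitter is full-batch gradient ascent, adequate up to
  a few hundred channels at desk scale but not tuned for very large N.
* The geometric null's matching cost is a documented stand-in for
  unavailable pseudocode (see above); its fidelity is established
  empirically by the distance-profile tests rather than by equivalence to
  the original implementation.
* No artifact rejection, line-noise notching, or seizure annotation: inputs
  are assumed to be curated inter-ictal segments.
* EDF input/output is not provided; recordings use the documented
  binary-array + JSON-sidecar container and delimited text formats.
* The optional refinement of initializing the null with high-error
  empirical regions is not implemented.
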