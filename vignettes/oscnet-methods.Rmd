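---
title: "Methods: frequency-resolved phase-synchronization connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-resolved phase-synchronization connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscnet)
```

## The analysis in one paragraph

oscnet estimates large-scale oscillatory networks from trial-epoched,
parcel-level electrophysiological time series recorded during a delayed
match-to-sample working-memory task with three conditions (Shape, Color,
Location) and two memory loads. Each epoch is decomposed with a complex Morlet
filterbank; phase synchronization between every parcel pair is estimated with
the imaginary phase-locking value (iPLV), pooled within analysis windows and
across trials; baseline-corrected connectomes are collapsed to a coarser
parcellation and tested edge-by-edge across subjects with the Wilcoxon
signed-rank test, followed by false-positive pruning and a simulated-null
density threshold; the retained graphs are summarized with graph metrics,
partitioned into leakage-consistent hyperedge bundles classified as shared or
condition-specific, and used to decode the memorized condition from
single-trial connectomes. Because raw recordings of this kind cannot be
redistributed, the package ships a synthetic-data generator with planted,
ground-truth couplings; every stage of the pipeline is validated against that
ground truth.

## Estimators

**iPLV.** For analytic signals with phases $\phi_i(t)$, the raw coupling of a
parcel pair is

$$\mathrm{iPLV}_{ij} = \left| \,\mathrm{Im}\, \frac{1}{N} \sum_{t}
e^{\,i(\phi_i(t) - \phi_j(t))} \right|,$$

pooled over the valid window samples of all trials of a condition
(single-trial variants pool over within-trial time points only). The
imaginary part discards all zero-lag consistency, which makes the estimator
blind to instantaneous linear source leakage; the absolute value makes raw
values non-negative, and signed effects (synchronization versus
desynchronization) re-enter through baseline subtraction. For a pair whose
phase difference is von Mises distributed with concentration $\kappa$ around
a lag of $\pi/2$, the estimator converges to the Bessel ratio
$I_1(\kappa)/I_0(\kappa)$ — the closed form used as the oracle in the tests.

**Filterbank.** Complex Morlet wavelets with time–frequency compromise
parameter $m = 5$: the temporal Gaussian has $\sigma_t = m /(2\pi f_0)$,
giving a relative spectral bandwidth of about $1/m$. Center frequencies are
spaced geometrically (the study's full bank is 38 wavelets, 3–120 Hz).
Filtering is FFT convolution with zero padding, scaled so that a sinusoid of
amplitude $a$ at $f_0$ yields analytic magnitude $a$; output is decimated to
$5 f_0$ by nearest-index selection.

**Windows and edge flagging.** Analysis windows are baseline
($-0.7$ to $-0.1$ s), early retention ($0.6$–$1.2$ s) and late retention
($1.2$–$1.8$ s) around the sample stimulus. Wavelets are truncated at
$\pm 3\sigma_t$ and every output sample whose wavelet support crosses an
epoch edge is flagged invalid and excluded from all statistics. At 3 Hz the
support ($\approx 1.6$ s) swallows the whole baseline window of a 2.7 s
epoch, so the lowest frequencies cannot produce baseline estimates — the
estimators raise an error there rather than return contaminated values.

**Bias matching across windows.** `|Im⟨·⟩|` has a positive small-sample bias
that shrinks with the number of pooled samples. Because edge flagging removes
more of the baseline window than of the retention windows, windows would
otherwise differ in bias and baseline subtraction would acquire a spurious
offset at every null edge. `matched_window_samples()` therefore trims every
window to the same number of contiguous valid samples (the minimum across
the three windows, at the native output rate) before estimation; the group
pipeline does this by default. With matched windows, pure-noise edges are
centered on zero after correction and the edgewise test is calibrated
(verified in the tests).

## Group statistics

Edgewise two-tailed Wilcoxon signed-rank tests at $\alpha = 0.05$ compare
baseline-corrected values against zero across subjects, on the coarse
(2-to-1 collapsed) parcellation and only over mask-surviving edges. The test
is the exact signed-rank distribution when there are no ties (the normal
approximation with tie and continuity corrections otherwise), vectorized over
edges; at $n = 20$ subjects its exact size is 0.0484.

**False-positive pruning.** All significant observations are pooled and the
$\lceil \alpha \cdot n_\mathrm{tests} \rceil$ least significant are discarded
— the number of discoveries expected to be false at level $\alpha$ over the
whole family. Two small-sample consequences matter and are handled
explicitly. First, with $n = 12$ subjects the smallest attainable two-tailed
p-value is $2 \cdot 2^{-12} \approx 4.9\times10^{-4}$, so all strong edges
*tie*; pruning therefore orders tied p-values by effect size (weakest
discarded first), otherwise the tie-break is arbitrary and can discard true
edges while keeping all-same-sign chance edges. Second, the discard count is
unconditional: when the true significant set is small (fewer significant
observations than $\alpha \cdot n_\mathrm{tests}$), pruning wipes the set
entirely — visible in the synthetic studies as a loss of sparse effects (for
example a handful of baseline-only theta couplings among ~430 tests), and a
genuine property of the procedure rather than a defect of the
implementation.

**Null density threshold Q.** The residual significant-edge fraction that
survives testing plus pruning under the global null is simulated directly
(i.i.d. standard normal subject-by-edge differences; the signed-rank test is
distribution-free under exchangeable signs, so the choice of null
distribution is immaterial). `Q` aggregates the per-simulation residual
fractions, by default with the maximum; observed networks are reported
against it. With the default rule, a fresh null dataset exceeds `Q` with
probability about $1/(n_\mathrm{sims}+1)$.

**Frequency clustering.** Each frequency's signed significance pattern
(+1 retained increase, −1 retained decrease, 0 otherwise) is vectorized;
adjacent frequencies are agglomerated (contiguity-constrained, average
cross-correlation linkage) while the best adjacent similarity exceeds a
cutoff (default 0.25). Frequencies with empty graphs correlate with nothing
and act as separators. Bands of at least two frequencies with retained edges
are reported as nontrivial.

## Leakage handling and subgraphs

The synthetic leakage model is a single zero-lag row-stochastic mixing matrix
built from a Gaussian kernel on a circular parcel layout; each parcel's
*fidelity* is the self-weight of its mixing row. Edges are excluded before
testing when either parcel's fidelity is below 0.165 or when the pair's
leakage radius — the cosine similarity of the two mixing rows, which equals
the zero-lag PLV induced by shared leakage of independent unit-variance
sources — exceeds 0.35.

**Hyperedge bundling.** Even with iPLV, a true lagged coupling reappears at
parcel pairs whose leakage neighborhoods contain the true endpoints. Bundling
groups such raw edges: the similarity of edges $(a,b)$ and $(c,d)$ is the
larger over endpoint pairings of $\cos(a,c)\cdot\cos(b,d)$ of mixing rows.
Clustering is *single linkage* (connected components at the similarity
cutoff, default 0.25): a spurious edge relates to its true edge through one
leakage step (one endpoint cosine, typically 0.3–0.5 at leakage levels where
bundling matters), whereas two spurious copies relate through two steps (a
product of two cosines, 0.1–0.15), so the smear around one true edge is a
connected component at a cutoff between those scales. Average linkage was
evaluated and rejected: it dilutes hub-centered smears below any cutoff that
still separates unrelated edges. With identity mixing every edge is its own
bundle. Bundles smaller than `min_size` (default 3) are discarded as likely
false positives.

**Shared versus specific.** The union graph combines the three conditions'
retained edges (weight: mean strength over the conditions in which the edge
is retained — the cross-condition mean reading of the union rule; the
per-condition alternative is a one-line change in `build_union`).
For each bundle, condition participations are the density-normalized shares
$p_c = (n_c/K_c) / \sum_{c'} (n_{c'}/K_{c'})$; a bundle is shared when at
least two conditions exceed the participation threshold (default 0.3; exact
ties count as exceeding, favoring shared), otherwise it is specific to the
condition with the largest share.

## Decoding

For each frequency, the largest `mask_k` entries of the group-average
retention-minus-baseline connectome define a binary edge mask applied to all
subjects and trials (on the study's full parcellation this is 1000 edges for
synchronization and all 400 parcels for amplitudes). Masked single-trial
iPLV vectors (retention = mean of the early and late windows) feed a random
forest (500 trees by default, square-root feature sampling), evaluated with
trial-level cross-validation: exact leave-one-trial-out, or the stratified
20-fold approximation as the desk-scale default (the retention-minus-baseline
contrast is preserved under either). The mask is computed from group
statistics of the same data, mirroring the study procedure; this shares
information across folds, which is why absolute accuracies are interpreted
only through the retention-minus-baseline contrast, tested per frequency with
a group Wilcoxon signed-rank test.

## The synthetic-data generator

`simulate_dataset()` produces 600 Hz epochs from −0.7 to +2.0 s around the
sample stimulus (the stated 2.7 s epoch length, with the late retention
window kept away from the epoch edge), with three conditions and two loads.
Each planted coupling is a pair of narrowband oscillators:

* both endpoints oscillate in **every** trial and window at constant
  amplitude (log-normal across trials); the window/condition scope gates only
  the phase *locking* of the second endpoint, crossfading between an
  independent phase walk and one locked to the first endpoint at the planted
  lag with von Mises jitter of concentration $\kappa$;
* every carrier has Brownian phase diffusion (default 5 rad²/s) and a
  per-trial frequency jitter (0.5 Hz), shared by the coupled pair;
* independent $1/f$ background noise is added and the whole trial is
  left-multiplied by the mixing matrix.

The first two choices are essential for honest nulls and were adopted after
diagnosing their absence, not to pass any particular threshold: perfectly
coherent same-frequency carriers never decorrelate within a trial, and
oscillators that switch off outside their window change the signal's
autocorrelation structure between windows — both turn into consistent
spurious baseline-corrected effects through the positively-biased
`|Im⟨·⟩|`, which the signed-rank test at $n = 12$ then detects. With the
always-on, diffusing model, pure-noise edges are calibrated (≈4–5%
rejection, centered on zero).

Planted effect sizes ($\kappa = 6$, carrier amplitude 1 relative to the
unit-variance noise) are free parameters of the generator, chosen once so
that single-edge power exceeds 0.8 at 12 subjects; the default topology
plants condition-specific alpha couplings inside condition-relevant visual
subdivisions (Shape→LOC, Color→V4/V8, Location→dorsal stream), shared alpha
couplings among dorsal-attention/fronto-parietal parcels, and baseline-only
theta couplings (retention-period desynchronization).

**What the generator does not emulate:** evoked responses, cross-frequency
coupling, amplitude–amplitude correlations, realistic inverse-operator
geometry (leakage is a one-step linear mix on a circular layout),
non-stationary noise, or behavioral learning effects. Passing tests
demonstrate that the estimators and statistics behave correctly under the
stated generative model — not that the pipeline is robust to everything real
recordings contain.

## Ground-truth accounting

With zero-lag mixing, a planted lagged coupling genuinely appears at parcel
pairs whose leakage neighborhoods contain the planted endpoints. These are
true lagged dependencies of the *observed* signals; no phase statistic can or
should reject them, and the pipeline's answer to them is bundling, not
edgewise exclusion. `recovery_rates()` therefore attributes retained edges
through the leakage model by default (an edge is false only if it cannot be
attributed to any planted coupling through the coarse mixing support);
strict accounting against the planted pairs alone is available via
`attribution = "strict"`.

## Problem sizes and determinism

The desk-scale default is 12 subjects, 60 fine parcels (30 coarse), 120
trials per condition, evaluated at the planted carrier frequency; the
full-size study design (20 subjects, 400 parcels, 800 trials, 38 wavelets)
is reachable through the same functions. The bundled validation studies use
smaller books (20–24 parcels) and fewer trials for the decoding and
clustering stages. All stages are deterministic given the seed: constructors
and simulators derive per-subject and per-stage child seeds, restore the
caller's RNG state, and regenerate subject data on demand so results do not
depend on evaluation order.

## Known limitations

* The pruning rule discards a fixed count $\lceil \alpha\,n_\mathrm{tests}
  \rceil$; sparse true effects (fewer significant observations than that
  count) are wiped entirely, and when the null significant count fluctuates
  above its expectation the excess slots are filled by the best-ranked null
  edges. Both behaviors follow from the procedure's definition.
* At 12 subjects the exact signed-rank p-value floor makes all strong edges
  tie; inference leans on the effect-ordered tie-break.
* Baseline estimates do not exist below ≈5 Hz for a 0.6 s baseline window
  with $m = 5$ wavelets (edge flagging), so the synthetic studies plant
  their low band at 5.8–6.5 Hz rather than at the bottom of the bank.
* Hyperedge bundling assumes the leakage (mixing) structure is known; with
  real recordings it must be estimated from the inverse operator, and label
  accuracy will degrade with estimation error.
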