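---
title: "Estimating temporally discounted cognitive maps from sequence learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating temporally discounted cognitive maps from sequence learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmap)
```

# The task and its latent structure

Participants respond to a sequence of 1000 cues drawn from a random walk on
a 10-node graph in which every node has degree 4, so first-order statistics
are identical across conditions and only the higher-order structure differs:

* the **modular graph** splits the nodes into two communities of five; all
  within-community pairs are connected except the pair of boundary nodes,
  and exactly two edges bridge the communities. This is the unique
  degree-4, minimal-cross-edge topology with two balanced modules on
  10 nodes, so the construction is forced even though only its defining
  properties are specified.
* the **ring lattice** connects each node to its nearest and next-nearest
  neighbours around a ring (a circulant graph with offsets 1 and 2).

`build_modular_graph()` and `build_lattice_graph()` construct these;
`transition_matrix()` gives the uniform random-walk kernel $A$ (every
nonzero entry $1/4$), and `random_walk()` draws seeded node sequences whose
stationary distribution is uniform. Nodes are indexed 1–10; the mapping of
nodes to on-screen stimuli is a stored permutation, which keeps the latent
and visual geometries distinct.

# The discounted-count learner

The core model assumes learners accumulate transition counts under an
exponentially decaying memory. When cue $x_{t+1}$ arrives, every past
position contributes to the remembered count of the pair
$(x_{t-\Delta t} \to x_{t+1})$:

$$\tilde n_{ij}(t+1) = \tilde n_{ij}(t) + \sum_{\Delta t = 0}^{t-1}
  \tfrac{1}{Z}\, e^{-\beta \Delta t}\,\delta(i = x_{t-\Delta t}),$$

with $Z = \sum_{\Delta t=0}^{t-1} e^{-\beta \Delta t}$ the finite geometric
sum, so each observed transition deposits exactly unit mass. This choice of
$Z$ (the normalisation is otherwise underdetermined) preserves the count
interpretation: total mass after $T$ trials is $T-1$, and in the
$\beta \to \infty$ limit the update reduces to exact counting of the most
recent transition. The finite-time estimate is the row-normalised count
matrix $\hat A_{ij}(t) = \tilde n_{ij} / \sum_k \tilde n_{ik}$; rows with no
mass yet are set to the uniform $1/n$, which makes the learner's prediction
well-defined from the second trial onward rather than discarding early
trials. In the infinite-data limit the estimate has the closed form

$$\hat A = (1 - e^{-\beta})\, A\, (I - e^{-\beta} A)^{-1},$$

a geometric mixture of multi-step transition kernels (the
successor-representation form). `map_analytic()` evaluates it by direct
solve; for $\beta \ge$ about $0.1$ the sup-norm distance to $A$ decreases
strictly with $\beta$, while below that it saturates at the uniform-limit
value. `anticipation()` runs the sequential learner (an $O(n)$ per-trial
recursion over per-node history weights, implemented in C++ and verified
against trial-by-trial accumulation of `update_counts()`) and returns
$a(t) = \hat A_{x_{t-1}, x_t}(t-1)$, the probability assigned to the
transition that actually occurred.

## Fitting the discount rate

Reaction times are modelled as $\hat r(t) = r_0 + r_1 a(t)$; for fixed
$\beta$ the coefficients are ordinary least squares and the objective is the
root-mean-square prediction error (the minimiser is identical whether the
sum or root-mean of squares is used; RMSE is reported for interpretability,
in seconds). `fit_beta()`:

1. evaluates the objective on 100 logarithmically spaced $\beta$ values in
   $[10^{-4}, 10]$;
2. refines the grid minimum by gradient descent in $\log\beta$ (central
   finite differences, step $10^{-4}$; backtracking line search halving up
   to 50 times; at most 500 iterations) until the absolute gradient falls
   below $10^{-6}$;
3. terminates with status `"zero"` if $\beta$ collapses below $10^{-6}$ and
   `"infinite"` if it exceeds 1000. Extreme fits carry flags rather than
   numeric 0/∞ so downstream statistics can exclude them.

Descent in $\log\beta$ (rather than $\beta$) makes the step size
scale-free across the four decades of the grid; the returned objective is
never allowed to exceed the best grid value. The fit is returned as a
classed model object with `print`, `summary`, `coef`, `predict`, `fitted`,
`residuals`, `simulate`, and `plot` (grid-objective curve) methods.

## Behavioural preprocessing

`filter_trials()` removes trials faster than 50 ms (too fast to be
stimulus-driven), slower than the participant mean plus 2 SD, and incorrect
responses. The mean and SD are computed once on the pre-filter table, which
avoids any dependence on exclusion order. `recency_covariate()` is the log
of the (capped at 10) number of trials since the current cue last appeared,
with first occurrences set to the cap — consistent with the saturation the
cap implies. `residualize_rt()` regresses reaction time on trial, stage,
finger, hand transition and recency by OLS; with a single participant the
random-slope mixed-model formulation collapses to exactly this regression,
and multi-participant tables should be residualized externally and passed
through. Covariate structure is removed exactly (residual correlations at
numerical zero), and collinear columns are dropped by the QR decomposition
with a warning.

# Representational similarity analysis

Epochs (`epoch_array`: channels × time × trials, with sampling rate,
per-trial labels and reaction times) are first brought to a common length by
`truncate_epochs()`: the length of the shortest trial, with a 200 ms floor
below which shorter trials are discarded. Stimulus alignment keeps the
first $L$ samples, response alignment the last $L$ before the response, and
middle alignment removes the centre (first $\lceil L/2\rceil$ plus last
$\lfloor L/2\rfloor$ samples).

`cv_euclidean_rdm()` computes, per condition pair, the leave-one-trial-out
cross-validated squared Euclidean distance: each fold takes the inner
product of the train-mean difference with a held-out-trial difference,
$\langle \bar x_a^{-f} - \bar x_b^{-f},\, x_{a,f} - x_{b,f}\rangle$, folds
pair held-out trials across conditions by index (the condition with fewer
trials cycles deterministically, so no extra randomness enters), and values
are divided by the vector length so entries are per-sample. This estimator
is unbiased — two conditions with identical generating means have expected
distance zero, so entries can legitimately be negative; that is the property
that makes the template correlations calibrated rather than
positively-biased. Internally all folds are evaluated through the trials'
Gram matrix, which is computed once per channel and merely re-indexed under
trial permutations; the implementation is verified against a direct
fold-loop oracle.

`template_corr()` is the Pearson correlation over the 45 strictly-lower-
triangle pairs, negated when the template carries similarity polarity (the
latent estimate $\hat A$, symmetrised, and the exact kernel $A$) so that
positive always means "geometry matches". Constant inputs raise an
undefined-correlation error rather than returning `NA` silently.

The null model (`circular_shift_null()`) rotates the trial order at a
uniform split $s \in \{1, \dots, T-1\}$ — data trials become
$(s{+}1,\dots,T,1,\dots,s)$ against labels in original order — preserving
the autocorrelation of the recording while destroying the label pairing;
the endpoints are excluded so every null differs from the observed
ordering. A channel is selected for the latent space when its correlation
beats at least 95 of 100 nulls *and* exceeds its correlation with the exact
kernel $A$; visual-space selection uses the null criterion only. With this
rule the expected false-positive rate on unstructured channels is a few
percent (measured ~3% at 100 permutations), which also bounds how often a
channel array can be recovered with *no* extraneous channel: with 17 noise
channels the probability of a perfectly clean selected set is only about
$0.97^{17} \approx 0.6$ per array. Sensitivity to genuinely structured
channels at SNR 2 is essentially perfect.

# Low-dimensional geometry

Dissimilarity matrices are embedded by classical MDS (`classical_mds()`,
double-centring and eigendecomposition via `stats::cmdscale`, padding with
zero coordinates when fewer than two nonnegative eigenvalues exist). The
latent estimate is a probability matrix, not a distance matrix, so it is
embedded by PCA instead (`pca_embed()`): rows as observations, columns
centred and scaled. The diagonal is zeroed before embedding: the walk never
repeats a node, so self-transition estimates carry no information about the
learned geometry, and dissimilarity matrices have structural zero diagonals
anyway. This choice matters — with the diagonal left in as a feature, the
embedded modules remain linearly separable at every discount rate, whereas
excluding it reproduces the characteristic regime change: module
discriminability (`lda_module_loss()`, the resubstitution misclassification
fraction of a two-class linear discriminant; with 10 points a held-out loss
is not estimable) is 0 for $\beta \gtrsim 0.15$ and jumps to 0.4–0.6 below
$\beta \approx 0.1$, where the boundary nodes swing toward the opposite
community. The discriminant is `MASS::lda` with a closed-form
ridge-regularised ($10^{-8}$) fallback for degenerate within-class
covariance; identical point clouds return chance loss 0.5.

# Temporal dynamics

`sliding_windows()` defines trial blocks (canonically width 500, step 100:
six blocks over 1000 trials, 1-based inclusive indexing).
`windowed_template_corr()` recomputes RDMs and template correlations within
each block, reusing the full-data trial length so windows are comparable,
and normalises each value by the channel's full-data correlation to expose
convergence rather than level differences. Blocks in which a condition has
fewer than two trials are reported missing. `windowed_beta()` refits the
discount model independently per block; each block restarts the count
accumulator and, when a behaviour table is supplied, re-residualises within
the block (window-local nuisance fits; extreme fits are reported as missing
values). `convergence_curve()` tracks the correlation between
$\hat A(t)$ and the analytic $\hat A$ along simulated walks: higher
discount rates converge faster, and at $\beta = 1$ the curve exceeds 0.9
well before the end of a 1000-trial session.

# Recording quality control

`channel_metrics()` computes line length (sum of absolute first
differences), kurtosis (z-scored across channels), and a PSD dissimilarity
(mean of one minus the Spearman rank correlation of smoothed periodograms
with every other channel, z-scored); `reject_channels()` flags line length
above three times the mean, or either z-score above 1.5, and channels whose
metrics are undefined (constant traces). Flags are equivariant under
channel reordering.

`detect_ieds()` implements a Hilbert-envelope discharge detector:
downsample to 200 Hz, 4th-order zero-phase Butterworth band-pass 10–60 Hz,
envelope as the squared magnitude of the analytic signal (computed in the
frequency domain), and a threshold of $k_0 (\mathrm{mode} + \mathrm{median})$
with $k_0 = 3.65$ in 5-second windows overlapping by 4 seconds, combined
across windows by per-sample OR. The mode of a continuous envelope is
estimated from a 64-bin histogram. One numerical subtlety: the power
envelope is heavy-tailed with its mode at zero, which would place the
threshold at roughly $2.5\times$ the mean and fire constantly; the
mode+median statistic is therefore computed on the amplitude scale, where
the background is Rayleigh-like and the resulting threshold sits near
$8\sigma$ — thresholding the power envelope at its square is equivalent.
$k_0$ remains configurable. Events are contiguous supra-threshold runs
timed at their envelope peak, and a spatial filter keeps only events
co-occurring within ±50 ms on at least three other channels, which removes
single-channel artifacts entirely. On the synthetic benchmark (20 channels,
120 s, 30 planted multi-channel spikes at SNR 5) sensitivity is 1.0 with no
false events on spike-free recordings. `notch_filter()` and
`car_reference()` are optional standard preprocessing hooks; nothing in the
analysis depends on them.

# The synthetic generators

The generators define the conditions under which every property above is
tested.

**Behaviour** (`gen_behavior()`): a 1000-trial walk; reaction times
$r(t) = r_0 + r_1 a(t) + \gamma\,\mathrm{recency}(t) + \varepsilon$ with
defaults $r_0 = 0.7$ s (typical median reaction time in this task family),
$r_1 = -0.3$ s (anticipated cues answered faster), Gaussian noise
$\sigma = |r_1|/4$ (the low-noise regime used for recovery checks; a
log-normal option exists for realism but is off by default since the
estimator is least-squares), recency effect $\gamma = 0.05$ s per log-trial
unit — large enough that residualization genuinely matters in tests —
accuracy 0.97, and a random stimulus-to-key assignment that induces finger,
hand and hand-transition covariates.

**Evoked epochs** (`gen_neural()`): a chosen template is converted to a
target *squared*-distance structure (similarity templates are flipped; a
Lingoes additive constant makes the structure exactly Euclidean without
breaking its affine relation to the template), embedded by classical MDS in
at most 9 dimensions, and the coordinates are tiled along the time axis of
each structured channel. Two deliberate choices: squared pattern distances
— not distances — track the template, because the analysis correlates
squared cross-validated distances against templates linearly, and a
generator faithful to the analysis should make that relation exact; and the
tiling (rather than a time-constant pattern) lets every structured channel
individually carry the full geometry, which per-channel selection requires
— a time-constant pattern would collapse each channel's geometry to one
dimension. SNR is the ratio of the mean condition-pattern norm to the
expected unit-noise norm over the stored window. Trial lengths come from
simulated reaction times; unstructured channels are pure Gaussian noise.

What the neural generator does **not** emulate: evoked temporal dynamics
(patterns have no meaningful time course), 1/f spectral structure or
autocorrelation within epochs, channel covariance, drift, or artifacts.
Passing the selection and geometry suites therefore demonstrates that the
estimators and the calibration of the null are correct under the assumed
signal model, not that real iEEG meets those assumptions; the QC module
exists precisely because real recordings violate them.

**Spike recordings** (`gen_ied_recording()`): pink-noise background with
biphasic 70 ms derivative-of-Gaussian transients (peak amplitude = SNR ×
background SD, spectral content inside the 10–60 Hz detection band) placed
synchronously on ≥ 4 channels with ≥ 0.5 s separation, collisions redrawn.

# Numerical choices and problem sizes

* β grid: 100 log-spaced points on $[10^{-4}, 10]$; descent tolerance
  $10^{-6}$ on the log-β gradient; extremes at $10^{-6}$ and $10^3$.
* Zero-count rows → uniform prediction; anticipation defined from trial 2.
* Truncation floor 200 ms; fold pairing cycles the shorter condition;
  null splits exclude the identity.
* Degenerate inputs: constant anticipation → zero slope with warning;
  constant template → error; degenerate LDA covariance → $10^{-8}$ ridge;
  sub-2-trial conditions → error (full data) or missing value (windows).
* Property suites run at the canonical sizes — 1000-trial walks, 20-seed
  recovery ensembles, 200 noise channels and 20 planted arrays at 100
  permutations, 120 s / 30-spike detector benchmarks — chosen to keep every
  check well-powered while completing in minutes on a single core.

# Known limitations

* **Recency-projection bias.** Residualizing reaction times on the recency
  covariate removes part of the anticipation signal itself (anticipation
  and recency are correlated by construction of the learner), which biases
  the recovered β upward — at $\beta_{true} = 1$ by roughly a factor of
  1.6–2 end-to-end, while ordering across learners is preserved. This is a
  property of the residualize-then-fit procedure, not of the estimator:
  fitting residuals simulated directly from the model recovers β to well
  within 50% at all tested values. Joint estimation of nuisance and
  anticipation terms would remove the bias at the cost of departing from
  the two-stage procedure this package implements.
* **Clean-set recovery is bounded by the null calibration.** The
  95-of-100-null selection rule admits ~3% of unstructured channels, so on
  arrays with many channels a perfectly clean selected set is unlikely even
  when sensitivity is perfect; consumers should treat the selected set as
  high-sensitivity, approximately-5%-FDR-per-channel, not exact.
* The analytic map assumes an infinite stationary walk; finite-sequence
  estimates differ early in learning (that difference is what the dynamics
  module measures).
* Single-participant OLS residualization ignores cross-participant pooling;
  multi-subject designs should residualize with a mixed model externally.
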