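---
title: "Predicting message-credibility decisions from source-space EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting message-credibility decisions from source-space EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credscan)
```

# The model and the pipeline

`credscan` predicts a binary single-trial decision — a participant judged
a message *credible* or *not credible* — from cortical current time
courses aggregated into brain regions. The experimental structure it
assumes has six observable cases, crossing the stimulus type with the
choice: true/false translations of a known sign judged (always correctly)
credible/not credible (TT, FF), and short or long notes on unknown signs
judged credible or not (ST, SF, LT, LF). Cases TF and FT do not occur by
design: participants are never wrong about signs they know, which makes
the known-sign pair a model of credibility evaluation under perfect
knowledge.

The pipeline has five stages.

**1. Charge features.** The input per trial is a nonnegative current
value per region per 5 ms bin over the post-stimulus epoch
$[0, 990)$ ms. The mean electric charge (MEC) per bin is the time
integral of current over the bin; since the data arrive as per-bin means,
the rectangle rule is exact for the representation we have:
$\mathrm{MEC}_{r,b} = I_{r,b}\,\Delta t$ with $\Delta t = 5$ ms.

**2. Per-participant normalization (sMEC).** Skull, meninges, skin and
hair attenuate the signal differently across people, so measured signal
power is participant-specific. Within each (participant, region) we
min–max scale MEC to $[0,1]$, pooling all of that participant's responded
trials and all bins:
$$s = \frac{x - \min}{\max - \min},$$
with a constant block mapping to 0 by convention. The pooling choice
matters: pooling across trials is what makes a participant-level
multiplicative gain cancel *exactly* (the test suite asserts invariance
to $10^{-12}$), while a per-trial normalization would also erase
trial-level amplitude information that carries class signal. Where the
normalization should sit relative to trial aggregation is genuinely open;
we normalize before any aggregation, because the classifiers are
single-trial and their features must be comparable across trials.

**3. The interval/region scan.** A candidate time window is any
half-open interval $[a, a+\ell)$ with $a$ on the 5 ms grid,
$a+\ell \le 990$, for each configured length $\ell$; there are
$(990-\ell)/5 + 1$ windows per length (194 for $\ell = 25$ ms). The
feature of a trial in a window is the *mean* of per-bin sMEC over the
window's bins, one value per region — a mean rather than a sum so that
features from windows of different lengths are on one scale and can
compete in the same search. Intervals are half-open so that "105–330 ms"
denotes an unambiguous set of 45 bins and adjacent windows do not share a
bin.

Within each window, regions are ranked by
$d(r) = |\bar{x}_r^{\mathrm{credible}} - \bar{x}_r^{\mathrm{not\,credible}}|$
computed on training trials only, ties broken lexicographically by region
label for cross-platform determinism. The top $Q = 5$ regions are kept
and every non-empty subset of them is one candidate logistic model:
$\sum_{q=1}^{Q} \binom{Q}{q} = 31$ candidates per window. `countModels`
does the exact accounting: unrestricted, $\binom{88}{5} = 39{,}175{,}752$
subsets per window and $2{,}261 \times \binom{88}{5} =
88{,}576{,}375{,}272$ models over the full scan; the top-$Q$ restriction
leaves $2{,}261 \times 31 = 70{,}091$. The exact set of window lengths
behind $I = 2{,}261$ is configuration (`scanConfig(lengths = ...)`), not
an assumption baked into code.

**4. Bootstrap selection.** Each candidate is scored by the mean
out-of-bag accuracy over $B$ bootstrap resamples of the training trials
(resample with replacement at the same size, refit, score on the trials
the resample missed; $B = 1000$ at full scale). The unit of resampling is
the trial: classification is single-trial, and the quantity being
estimated is trial-level generalization within the training participants.
The winner — ties broken toward fewer regions, then earlier window start,
then lexicographic region labels — is refit on all training trials.

**5. Held-out evaluation.** Participants are split into training and
validation sets *before* any of stages 3–4; every participant's trials
land wholly on one side, so no validation information can shape the
search (the evaluation refuses participant overlap outright). The final
model is applied once to the validation trials at threshold 0.5, with
"credible" as the positive class for precision/recall/F1 — credibility is
the construct of interest, and F1 depends on this choice, so it is stated
prominently. A threshold-swept ROC and trapezoidal AUC make the threshold
choice transparent.

Alongside the classifiers, the behavioral module computes the long- and
short-note credibility proportions, the exact two-sided binomial test of
choice randomness (two-sided because the null — choices binomially random
at $p_0 = 0.5$ — is undirected), and the LC/SC grouping: per participant,
the ratio of long-note to short-note credibility endorsements among
unknown signs, with the "long-note-preferring" group defined by a ratio
strictly above the mean of the defined ratios. Participants with
$SC = 0$ have an undefined ratio and are excluded from the mean rather
than given an infinite one.

# The synthetic-data generator

No public recording of the original cohort exists, so the package ships a
generator whose defaults encode the experiment's structure: 105
participants; per participant 240 trials in three groups of 80
(known-sign short notes split 40 true / 40 false, unknown-sign short
notes, unknown-sign long notes); choices for known signs deterministic,
for unknown signs Bernoulli at the observed rates 0.536 (long) and 0.409
(short); per-condition completion counts 105/104/95, modeled as the
trailing participants lacking that condition pair; epoch $[0, 990)$ ms at
5 ms bins over 88 regions (left/right Brodmann parcels plus both
hippocampi).

Trial currents follow
$$I_{r,b} = g_p \cdot \max\!\bigl(0,\; \mu + \sigma z_{r,b} + e_{r,b}\bigr),$$
with participant gain $g_p \sim U(0.5, 2)$ (the individual SNR difference
that motivates sMEC), baseline $\mu = 1$, and $z$ a unit-variance AR(1)
Gaussian process over bins with lag-one correlation $0.8$ — smooth,
nonnegative after rectification, and with an analytically trivial
constant-signal limit at $\sigma = 0$. Planted effects $e$ are additive
Gaussian-in-time bumps confined to a window (SD one quarter of the window
width), applied to the elevated case of one condition pair, with peak
amplitude expressed in units of $\sigma$; this is the simplest dynamic
under which "the window with the largest class difference" is
well-defined ground truth. Default planted windows (105–330, 330–530,
830–855 ms for the short/known/long pairs) mirror the windows the search
is expected to find, so the demonstration reproduces the intended
narrative shape. Non-response within the 3.5 s limit is a per-trial
Bernoulli flag (default rate 0); non-responding trials are excluded from
features and counts.

What the generator deliberately does *not* emulate: raw 500 Hz
multichannel EEG, artifacts, volume-conduction correlations between
regions, eye movements, or reading-time structure. Passing tests
therefore demonstrate that the *pipeline* recovers what it is designed to
recover under a clean, known ground truth — not that the published
accuracies would reproduce on new human data, which remain unavailable.

The optional inverse module is the same kind of stand-in: a standardized
minimum-norm (Tikhonov-regularized, average-referenced, standardized by
the diagonal of the resolution operator) on deterministic toy lead fields
with fixed-orientation scalar dipoles. It is a desk-scale mathematical
equivalent of the source-localization stage, not a head-model
replication; the downstream pipeline needs only region × bin currents.
Magnitudes (not signed currents) are exported, since charge-like features
are nonnegative. Its tested properties — exact single-dipole localization
in the noiseless small-regularization limit, reference invariance,
agreement with an independently constructed pseudo-inverse operator — are
the properties the standardized minimum norm is used for.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `binMs` | 5 | ms | grid of the delivered data; finer would average away changes, coarser hides them |
| epoch | [0, 990) | ms | post-stimulus window; 990 is the value consistent with 194 windows of 25 ms |
| `lengths` | configurable | ms | the scanned window lengths; exposed because the full-scale set is not recoverable |
| `maxRegions` (Q) | 5 | regions | models beyond 5 regions showed no accuracy gain in the antecedent work |
| `B` | 1000 (full), 100 (reduced) | resamples | bootstrap repetitions; 100 keeps desk-scale experiments tractable |
| split | e.g. 78/27 | participants | participant-level, matching the full-scale design |
| `gainRange` | [0.5, 2] | — | plausible inter-individual SNR spread |
| `noiseSd`, `noiseAr` | 0.3, 0.8 | — | moderate per-bin variability with realistic temporal smoothness |
| amplitude | per effect | baseline SD | planted effect size on a scale-free unit |

# Numerical and implementation choices

- **Logistic fits** are plain maximum-likelihood Newton/IRLS, run in
  compiled code; the test suite pins the coefficients to `stats::glm` at
  $10^{-6}$. Under (quasi-)complete separation — which subsets of up to 5
  features on small cohorts do produce — the fit falls back to a small
  ridge penalty ($\lambda = 1$ on non-intercept terms), keeps the
  coefficients finite, warns, and flags the model.
- **The bootstrap engine** advances all $B$ refits of one candidate
  together, warm-started from the full-data fit, dropping refits whose
  Newton step falls below $10^{-4}$; one shared set of resamples serves
  all candidates in a selection run (a paired comparison, which also
  removes resampling noise from the between-candidate ranking). Resample
  indices are always drawn from R's RNG, so a single seed reproduces a
  search bit-for-bit.
- **Degenerate inputs**: constant (participant, region) blocks map to
  sMEC 0; empty out-of-bag sets are skipped and counted; single-class
  validation sets yield `NA` metrics with an explicit `undefined` list
  rather than silent zeros; misaligned intervals, unmapped dipoles,
  unknown configuration keys and participant overlap between training and
  validation are errors, not warnings.
- **Exact integer accounting** in `countModels` uses double precision
  (exact through $2^{53}$) and refuses larger counts.

# Problem sizes in the test suite

The stochastic end-to-end experiments run at sizes chosen to make a
desk-scale machine sufficient while keeping the estimates meaningful: the
recovery experiment uses 20 independent cohorts of 60 participants
(10 long-note trials each, 12 regions, one 2-region effect of amplitude
1.5 SD at 300–400 ms), a 45/15 participant split and the reduced scan
(lengths 50 and 100 ms, $B = 100$); the null calibration uses one
effect-free cohort of 105 participants (95 completing the long pair)
with 24 trials each and a 50/45 split, giving 1080 held-out trials. The
null cohort sets both choice rates to 0.5 so that chance accuracy is
exactly 0.5 and the calibration band $[0.45, 0.55]$ isolates selection
optimism; with the default long-note rate of 0.536, a signal-free
classifier legitimately scores about 0.536 through the base rate alone,
which a band centred at 0.5 would misattribute to leakage.

# Known limitations

- One window per model: all regions of a candidate share the same time
  interval; per-region windows are out of scope.
- Fixed-orientation dipoles and toy geometry in the inverse module; no
  realistic BEM/FEM head model, no 256-channel montage.
- The restricted top-$Q$ search is greedy in the ranking: a region pair
  that is jointly but not marginally informative can be missed.
- Published-model fixtures carry the reported metrics as reference
  metadata only; nothing in this package can re-derive them without the
  original recordings.
- Reported full-scale splits (78/27, 78/26, 74/21) sum to 105/104/95;
  the generator reproduces those counts, but which participants dropped
  is unrecorded, so attrition is modeled deterministically by index.
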