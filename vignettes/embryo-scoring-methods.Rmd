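---
title: "Pseudo-contrastive embryo scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-contrastive embryo scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(embryopcl)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic cohort generator does and does not emulate, and the design
choices made where the method left room.

## The supervision problem

A time-lapse incubator yields hundreds of frames per embryo, but labels
are scarce and structurally noisy:

* only transferred embryos (a small minority) acquire Known Implantation
  Data (KID) tags, and multi-embryo transfers with partial implantation
  leave every transferred embryo ambiguous (KIDu);
* a KIDn tag does not prove a bad embryo — implantation can fail for
  maternal reasons — so negative labels carry noise;
* implantation odds fall with oocyte age, so age confounds any naive
  comparison of embryos across patients;
* embryo appearance changes drastically across five days of development,
  so a single classifier sees wildly heterogeneous inputs.

The package addresses these with four mechanisms: a margin loss robust to
label noise, pairwise pseudo labels that recruit unlabeled embryos, an
oocyte-age gate on comparisons, and time-conditioned prediction heads.

## Losses

Everything trains with the binary soft hinge
$$l(s, y) = \log\!\left(1 + e^{\gamma (m - y s)}\right),\qquad
y \in \{-1, +1\},$$
a smooth upper bound of the margin hinge. Defaults $m = 1$, $\gamma = 1$;
with $m = 0$, $\gamma = 1$ it is exactly the logistic negative
log-likelihood (`soft_hinge()` has a unit test pinning this identity to
1e-12). The margin keeps confidently-correct samples from dominating
gradients, which matters under label noise.

For segmentation the per-pixel loss is multiplied by a focal-style weight
$$w_p = \frac{e^{-s_p y_p}}{\sum_{q: y_q = y_p} e^{-s_q y_q}},$$
normalized so foreground and background each carry one unit of weight
(`pixel_weights()`), and summed (`segmentation_loss()`). Already-correct
pixels are down-weighted; the per-class normalization absorbs the heavy
foreground/background imbalance of embryo masks. As printed in its source
the weight's denominator repeats the numerator's index (which would reduce
every weight to $1/|{\rm class}|$ and contradict the stated purpose of the
term); the package normalizes over the class members' own scores, which is
the reading under which the unit-weight property is meaningful. Weights
are treated as constants in the gradient (no backpropagation through the
normalizer), the focal-loss convention.

## Time-conditioned classifier

One prediction head per 2-hour window of the inspected interval
$\Delta_t = (30, 120)$ hours post fertilization gives 45 heads
(`head_config()`); windows are right-open with the endpoint folded into
the last head, so every admissible time maps to exactly one head. At
inference only the head owning the frame's acquisition time is read
(`score_frames()`).

The desk-scale backbone (`classifier_config(backbone = "tiny")`) is a
small multi-head network designed around what ~100-embryo cohorts can
support:

* a fixed two-channel stem — block-averaged intensity and block-averaged
  gradient magnitude (texture/edge energy, invariant to global
  illumination) on a 16×16 grid over the 64×64 mask-centred crop;
* one shared trainable hidden layer (ReLU, width 16);
* a **shared readout plus a per-head correction**, both zero-initialized.

The last point is a deliberate deviation from fully independent per-head
layers: at desk scale, independently-trained heads can converge with
inconsistent sign/scale across time windows, and temporal integration
then *degrades* the frame scores it is meant to smooth. The shared readout
keeps score polarity consistent across windows while the per-head
corrections retain time conditioning; zero-initialized readouts make an
untrained head neutral rather than random. Clinical-scale backbones
(ResNet-class CNNs on millions of frames) are out of scope for this
package.

Training (stage A, `train_model_a()`) is Adam on the summed soft hinge
over KIDp/KIDn frames, all focal planes as independent samples, weight
decay 1e-5, with per-frame brightness jitter (sd 0.15) and feature noise
(sd 0.06) as augmentation — the desk-scale substitute for clinical data
diversity, and the same role the seven focal planes play as natural
augmentation at full scale. The loss reduction is a sum, not a mean, so
the default learning rate (3e-3) is tuned to the default batch size (24).

## Temporal integration

Frame scores are fused by a first-order ARMA recursion
$$B_t = \alpha A_t + (1 - \alpha) B_{t-1}, \qquad \alpha = 0.05,$$
initialized at the first raw score — zero initialization would inject an
arbitrary pull toward 0 lasting roughly $1/\alpha$ frames, while
first-score initialization keeps every output an exact convex combination
of the inputs seen so far (a tested invariant). The recursion steps once
per available frame; missing frames are skipped, not imputed. The embryo
score is the value at the last time point (`embryo_score()`).

$\alpha = 0.05$ presumes hundreds of frames: after $n$ frames the first
frame retains weight $(1-\alpha)^{n-1}$, which is ~0 at the clinical
360–480 frames but still 0.22 at 30 frames. Desk-scale cohorts therefore
use a 1-hour frame interval (90 frames) so the coefficient operates in its
intended long-memory regime.

## Pseudo-contrastive pairing

Given a frozen teacher's end-point integrated scores, a pair (i, j) gets
$$y_{ij} = \begin{cases}
+1 & B_i - B_j > \theta \text{ and } j \text{ not KIDp}\\
-1 & B_j - B_i > \theta \text{ and } i \text{ not KIDp}\\
0 & \text{otherwise,}
\end{cases}$$
and the student minimizes $\sum l(C(x_i^{t_i}) - C(x_j^{t_j}),\, y_{ij})$
over all embryos, labeled or not (`pair_label()`, `pair_loss()`,
`train_student()`). Known positives can never be pushed to the losing
side, which is the mechanism that tolerates noisy negatives. Frames in a
pair need not share a timestamp. Design choices:

* **Unordered pairs, counted once.** The double sum over ordered pairs
  contributes two identical terms per pair, since
  $l(s_{ij}, y_{ij}) = l(-s_{ij}, -y_{ij})$ for the soft hinge; single
  counting halves compute and rescales the loss by a constant. A
  `double_count` flag restores the literal double sum.
* **$y = 0$ pairs are dropped**: under the soft hinge they contribute the
  constant $\log(1 + e^{\gamma m})$ with zero gradient.
* **Age gate.** Pairs must satisfy $|age_i - age_j| \le \theta_o$ with
  $\theta_o = 2$ years — about half a standard deviation of clinical
  oocyte ages — so that ranking signal cannot come from the age
  confounder. Batches are age-similar by construction: an anchor embryo is
  drawn and the batch filled with the nearest-age embryos (falling back to
  nearest when the stratum is thin); the per-pair gate is still enforced.
* **One random (frame, focal) per embryo per batch**, batch size 24.
* **Teacher scores are frozen per round**, computed once on the central
  focal plane at the last time point; the cascade runs exactly two rounds.

### The score-gap gate $\theta$

$\theta$ trades pair coverage against teacher noise: too large dismisses
nearly all pairs, too small overfits the teacher's errors. It is estimated
from the two 100-bin histograms of teacher end scores on the KIDp and KIDn
training sets: for every bin index populated in both histograms, take the
difference of the bins' mean scores, and average (`estimate_theta()`).
Each class is binned over its own score range and bins are matched by
index. This reading has the property that an elementwise shift
$neg = pos - \delta$ is recovered exactly ($\theta = \delta$); binning
both classes over common pooled edges would instead bound every per-bin
difference by one bin width and make the estimate collapse toward zero.
Degenerate cases: a zero-width score range collapses to one bin; if no bin
index is populated in both histograms the estimate falls back to the
difference of class means; the result is clamped at zero. $\theta$ is
re-estimated before each pseudo-label round (from B for training C, from
D for training E).

## Segmentation and cropping

The desk-scale segmenter is a pixelwise linear scorer over a fixed
multi-scale local feature bank — intensity, box means at three scales,
local standard deviation, and a centre-surround contrast channel — i.e. a
1×1 convolution trained over a filter-bank front end, with the weighted
soft-hinge objective and Adam (`train_segmenter()`). One step consumes one
frame; weights are recomputed each step. This is sufficient for the
generator's well/embryo geometry (held-out per-pixel accuracy above 0.9 in
the tests); an encoder–decoder is unnecessary at this scale.

Detection metrics follow the IoU working bands: predicted positives are
split into 8-connected clusters (the method's source does not define
"cluster"; 8-connectivity of the thresholded score map at 0 is this
package's choice); the largest cluster's IoU with the ground truth defines
a true positive above 0.9, and any cluster below 0.5 counts as a spurious
false-positive detection (`detection_metrics()`). Per-pixel accuracy at
evaluation is conventionally computed relative to each embryo's bounding
sub-image; the package's tests compute it on full frames, which is the
stricter reading under heavy background majority.

`crop_embryo()` cuts a square window centred on the mask centroid, sized
to the mask bounding box plus a 15% margin, pads out-of-frame regions with
the median border intensity (no reflection artifacts), and resizes. The
centring and padding conventions are this package's; only the crop-then-
classify structure is inherited.

## The synthetic cohort generator

`generate_cohort()` emulates the *statistical* structure the method
relies on, not embryo appearance:

* **Latent viability** per embryo, Beta-distributed with mean decreasing
  in oocyte age (the confounder the age gate must neutralize) and a low
  concentration (3) giving a broad quality spread — with a tight spread,
  the top-of-patient transfer selection restricts the labeled embryos'
  range so severely that desk-scale supervised learning is impossible by
  construction.
* **Viability is visible two ways**: as morphokinetics (a
  viability-dependent developmental clock across the 1→2→4→8-cell,
  compaction and blastocyst-expansion schedule, plus possible arrest at a
  random stage) and as a static appearance cue (interior brightness and
  texture energy), so single-frame classifiers can learn at any time
  point. The amplitudes are set so that the cue is learnable from tens of
  labeled embryos, which is what a 200-embryo cohort provides after label
  hiding.
* **Frame-level nuisance**: a global illumination jitter per captured
  image — exactly the noise temporal integration is meant to average out —
  plus per-pixel noise and focal-dependent blur.
* **Label machinery**: per simulated patient the top-viability embryo(s)
  are transferred (two with the configured probability); implantation is
  Bernoulli in viability, with a non-embryonic failure probability that
  injects the clinical KIDn noise; single transfers yield KIDp/KIDn,
  double transfers with exactly one sac yield KIDu for both; everything
  else is notKID with the lowest-viability subset flagged hard-discarded.
  Splits are assigned per patient, so no patient spans two splits. The
  latent truth is returned separately and never written into the manifest.

What it does **not** emulate: pronuclei, fragmentation, photorealistic
texture, clinic-specific imaging differences, or inter-observer grading
variability. Passing tests on this generator demonstrate that the
training machinery extracts and amplifies a viability signal under the
clinical label structure — not that it would reach any particular accuracy
on real clinical images.

The manifest is one CSV row per frame with embryo metadata repeated
(columns documented in `?cohort_manifest`); frames carry independent
timestamps and focal planes, and a single delimited file keeps cohorts
streamable. The "Discarded" evaluation set is defined as all notKID
embryos, with `hard_discarded` the flagged subset, since the manifest
schema carries a single discard flag.

## Evaluation

`auc()` is the Mann–Whitney statistic with midrank ties (cross-checked
against pROC), `auc_over_time()` evaluates each embryo's latest score at
or before each grid time (carrying the earliest score back before the
first frame), `auc_by_age()` flags rather than drops under-populated bins,
and `score_report()` produces the per-stage, per-day (72 h / 114 h) table
against the four negative sets. The 114-hour day-5 endpoint matches the
culture period over which complete clinical test data exist.

`select_threshold()` minimizes the summed FP and FN counts with the
prediction-positive convention `score >= tH`; candidate thresholds are
midpoints between consecutive sorted unique scores plus sentinels below
and above the range, which realizes every achievable confusion matrix.
Ties break toward the smallest threshold — the more sensitive working
point; the objective is flat between the tied candidates, so this is a
reporting convention, not a performance choice. The reported
`accuracy_01` is the 0–1 *error* (misclassification rate), matching the
working-point tables this layout mirrors.

## Reference evaluation protocol and problem sizes

End-to-end behaviour is measured on a fixed reference condition
(`reference_synth_config()`): 200 embryos, 64×64 frames, one focal plane,
1-hour frame interval, half the cohort transferred, non-embryonic failure
probability 0.2, with **70% of the train/val KID labels hidden** before
any training (`hide_kid_labels()`). Hiding makes the semi-supervised
mechanism load-bearing: stage A sees only ~12 labeled embryos, while the
pair stages see all ~120 training embryos. Held-out evaluation uses every
KID-labeled embryo whose label no trained stage ever saw — the hidden
embryos plus the test split (`heldout_kid_auc()`) — at the 114-hour
endpoint, over three seeded replicate cohorts, comparing medians. These
sizes keep a full three-replicate evaluation within minutes on one CPU
while leaving ~40 held-out labels per replicate; single-replicate AUCs at
this size carry sampling noise of several points, which is why medians
over replicates are the reported quantity.

Under this protocol the cascade reproduces the method's qualitative
claims: temporal integration does not hurt (B vs A, D vs C, F vs E), and
the final integrated model F improves on the supervised seed stage A —
the gain realized by recruiting the unlabeled majority through
pseudo-contrastive pairs. `scripts/acceptance.R` recomputes all of it
from scratch.

## Known limitations

* The backbone is intentionally tiny; absolute AUCs on the synthetic
  reference (≈0.6–0.8) are not comparable to clinical-scale results.
* With ~12 visible labels, stage A remains seed-sensitive; conclusions are
  drawn from medians over replicate cohorts, mirroring how the stochastic
  tests are written.
* θ estimation inherits the teacher's calibration: a teacher that
  overfits its labeled embryos inflates θ and starves the pair stages.
  Augmentation keeps this in check at desk scale.
* The generator's arrest/progression model is a caricature adequate for
  testing label machinery, not for biological inference.
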