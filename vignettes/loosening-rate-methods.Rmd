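---
title: "Loosening-rate detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loosening-rate detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loosenrate)
```

## The problem and the model

Cured tobacco leaves arrive at a sorting line in tied bundles that must be
loosened — spread so individual leaves separate — before grading. An object
detector watching the belt reports two classes per frame: `stem`, a single
visible tobacco stem, and `bunch`, a region of overlapping stems (a bundle
not yet pulled apart). This package turns those detections into a per-bunch
judgement.

The procedure is deliberately simple. After dropping detections with
confidence below a cutoff, each stem box that overlaps a bunch box with
strictly positive area is counted as a member of that bunch; the member
count is $x$. With an operator-set maximum $\lambda$ (how many stems a
normally loosened bunch may still contain), the loosening rate is

$$R = \frac{\lambda}{x} \times 100\%.$$

A bunch is *qualified* iff $x < \lambda$, equivalently $R > 100\%$. The
quantity of interest at evaluation time is whether unqualified bunches are
flagged: the positive class is the unqualified bunch, and precision, recall,
F1 and per-predicted-class accuracy are computed on the bunch-level
confusion matrix.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `lambda` | 8 | Max member stems for a qualified bunch; set by line staff. With 8, a 7-stem bunch passes ($R = 114\% > 100\%$) and an 8-stem bunch fails ($R = 100\%$). |
| `conf_threshold` | 0.30 | Detection confidence cutoff, kept with `>=` so a boundary detection survives. 0.30 is the F1-maximizing operating point of the reference deployment sweep (`sweep_metrics(field_sweep_counts())`). |
| `multi_overlap_rule` | `max_intersection` | Where a stem overlapping several bunches counts. The field situation the rule must cover is a stem at the seam of two bundles; assigning it to the bunch it overlaps most (ties to the lowest index, making the result deterministic) keeps $\sum_b x_b$ at most the stem count. `all` double-counts instead. |
| `iou_match_threshold` | 0.5 | IoU needed to pair a detected bunch with a ground-truth bunch (greedy, confidence-descending, one-to-one) before tallying verdicts. |

Two edge cases are decisions, not consequences of the rate formula. A bunch
box with $x = 0$ (the detector resolved no members) gets verdict
*qualified* with a warning — an undefined rate must not crash a production
pipeline, and flagging a bunch whose contents are unknown would alarm on
every stray box. Edge-contact (zero-area) overlap counts as no overlap,
consistent with the area-based overlap measure used everywhere else.

## Losses and fusion arithmetic

The regression losses the detector trains with are provided as pure
per-pair scalars so that their arithmetic is verifiable in isolation;
batching and reduction over anchors belong to the caller.

CIoU adds to $1 - \mathrm{IoU}$ a center-distance penalty $\rho^2/c^2$
(squared center gap over squared enclosing-box diagonal) and an
aspect-ratio term $\alpha v$. At a perfect match both $v$ and $1 -
\mathrm{IoU}$ vanish and $\alpha$ becomes $0/0$; the implementation takes
the limit, $\alpha v = 0$. WIoU v1 instead multiplies $1 - \mathrm{IoU}$ by
$\exp\!\big(\rho^2 / (W_g^2 + H_g^2)\big)$; in its original formulation the
denominator is detached from the gradient, which a scalar library honors by
reporting $W_g^2 + H_g^2$ among the result components so an autodiff
consumer can detach it. WIoU v2 multiplies v1 by the monotonic focusing
coefficient $(L_{\mathrm{IoU}}/\bar L_{\mathrm{IoU}})^{\gamma}$, where
$\bar L_{\mathrm{IoU}}$ is an exponential moving average over observed
pairs. The mean starts at 1, is read *before* and updated *after* each
evaluation, and is floored at $10^{-8}$ because the coefficient is
undefined at mean zero. Neither $\gamma$ nor the momentum is part of the
loss's definition (published releases differ), so both are configuration:
$\gamma = 1$, momentum $0.01$ by default, and $\gamma = 0$ recovers v1
exactly. GIoU, DIoU, EIoU and Focal-EIoU (focusing exponent 0.5) are
included from their published closed forms as comparators in a registry
extensible with `register_bbox_loss()`.

All losses are zero exactly at a perfect match and invariant to joint
translation and joint scaling of the pair — the property suite checks both
on randomized boxes.

The feature-pyramid fusion used in bidirectional necks is
$\mathrm{transform}\!\big(\sum_i w_i P_i / (\sum_i w_i + \epsilon)\big)$
with weights clamped non-negative (learned weights can drift below zero)
and $\epsilon = 10^{-4}$, the customary stabilizer. Resize contracts
default to nearest-neighbour doubling (top-down) and $2\times 2$ mean
pooling (bottom-up); the transform defaults to identity, since the
contribution here is the weighted fusion, not the convolution around it.
Whether fusion weights are shared between pathways is unspecified in the
neck's usual description; nodes here own their weights.

## What the synthetic generator emulates

`generate_scene()` emulates one 2448×2048 belt frame (the acquisition
camera's resolution): bunch boxes are placed mutually disjoint, each
containing its specified number of member stems, plus isolated stems
overlapping no bunch. Because membership is then unambiguous, the true
$x$ per bunch is exact by construction and the noiseless round trip
(`corrupt_scene(scene, zero_noise())` → `assess_scene()`) must recover
every count and verdict — which is what the end-to-end tests assert.

`noise_model()` layers on detector imperfection: independent misses
(default `p_miss = 0.05`), Gaussian corner jitter (4 px, re-clamped to keep
boxes valid and inside the frame), and Poisson-many spurious stem boxes per
scene (rate 5). Spurious boxes fall inside a bunch box with probability 0.7
— detectors hallucinate precisely in occluded, cluttered regions, and this
is what makes a low confidence cutoff expensive: admitted phantoms inflate
$x$ and flip borderline qualified bunches. Confidences come from Beta(8, 2)
(mean 0.8) for true and Beta(3, 7) (mean 0.3) for spurious detections.
These two shapes are a test fixture, not a measured detector property; they
give the cutoff something to trade. Under these defaults the pooled F1
confidence sweep rises to an interior maximum and falls — low cutoffs pay
in precision, high cutoffs starve recall — reproducing the qualitative
shape that motivates operating-point selection. The unimodality check
tolerates 0.01 of F1 per step, the counting noise expected from pooled
integer confusion counts at this problem size.

Bunch sizes default to uniform on 2–14, straddling $\lambda = 8$, so both
verdicts and near-boundary cases occur; the real size distribution on a
line is not tabulated anywhere usable, and a uniform straddle is the
choice that exercises the decision boundary hardest. What the generator
does *not* emulate: photorealistic appearance, correlated misses under
heavy occlusion, duplicate detections of one object, and frame-to-frame
tracking. Passing tests therefore certify the algorithmic pipeline, not
detector performance on real imagery.

## Numerical and interface choices

* Boxes are continuous, corner-based, origin top-left, y down. Normalized
  center-format label files are converted at the I/O boundary; writers keep
  six decimals, so round trips are exact to $10^{-6}$ of the frame.
* Degenerate (zero/negative-area) boxes are rejected with errors
  everywhere, including inside loss functions; readers refuse malformed
  lines with the file and line number rather than coercing.
* Average precision uses all-point interpolation (the precision envelope
  integrated over recall), matched against an exhaustive step-curve oracle
  in tests; matching is greedy one-to-one in descending confidence at IoU
  $\ge 0.5$ within class.
* Bunch tallying conventions: a detected bunch with no ground-truth
  counterpart carries an implicit *qualified* truth (flagging it as
  unqualified is a false positive); a missed ground-truth bunch carries an
  implicit *qualified* prediction (an unqualified one the detector never
  saw is a false negative). These conventions are what make the bundled
  40-bunch deployment record (37 matched + 2 spurious + 1 missed) tally to
  its published counts.
* Determinism: every stochastic routine takes a seed; dataset generation
  derives per-scene seeds from the master seed, so reruns are
  byte-identical.

## Problem sizes used in the checks

The shipped verification suite uses: 1000 randomized pairs for the loss
property suites, 500 random scenes of up to 200 objects for the
association-vs-brute-force equivalence, 100 seeded noiseless scenes (a few
hundred bunches) for exact end-to-end recovery, and 60 noisy scenes pooled
per threshold for the sweep-shape property. These sizes give stable pooled
counts while keeping the whole suite fast on a laptop.

## Known limitations

* The rate depends entirely on detector output; systematic detector bias
  (e.g. under-detecting stems in dense bunches) directly biases $x$
  downward and inflates apparent loosening quality.
* A stem bridging two bunches is counted once by a geometric heuristic;
  no appearance information arbitrates the tie.
* Bunches are assessed per frame; the same physical bunch seen in several
  frames is assessed several times (no tracking).
* The $x = 0$ convention (qualified with a warning) is deliberately
  permissive; lines that prefer alarms on unresolved bunches should treat
  the warning as a signal.
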