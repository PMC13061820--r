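---
title: "Spatio-temporal scan-plane classification: models, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal scan-plane classification: models, pipeline, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A liver ultrasound exam is acquired as five protocolized probe sweeps
("scans"), each visiting a predefined ordered sequence of anatomical
landmarks.  Scan-plane detection assigns each moment of the video to one
of six standard planes (Portal Bifurcation, Hepatic Vein, Gallbladder,
Heart, Kidney, Ilo) or to a background class ("Other").  Some planes are
hard to recognise from a single frame but easy from a short sequence —
the heart is the canonical example: its rhythmic pulsation is invisible
in a static image and obvious across ten consecutive frames.  This
package implements a family of convolutional classifiers that exploit
that temporal structure while staying light enough for portable devices.

## The architectures

All variants share the same skeleton, a VGG16-derived trunk with the
fully connected head replaced by pointwise convolutions:

* **Feature extractor** — 13 convolution slots in blocks of 2-2-3-3-3
  with a max-pooling after each of the first four blocks (17 layers in
  total).  Every convolution is 3x3 (3x3x3 in 3D), stride 1,
  same-padded, bias-free, and followed by batch normalisation and ReLU.
  Widths start at the base width `B` and double after each of the first
  three pools; the fifth block stays at `8B`.  A literal doubling after
  *every* pool would give a different model: the `8B` plateau is the
  only plan whose closed-form counts reproduce the published budgets of
  all three 2D base widths (930,334 / 3,715,630 / 14,851,150 for
  B = 16/32/64), so the plateau is taken as the intended architecture.
* **Adaptation module** — 1x1 convolution `8B -> 4B` (BN, ReLU), 1x1
  convolution `4B -> C` (BN), global average pooling over all remaining
  positions, softmax.  This is the unique simple two-convolution layout
  whose parameter total (33,934 for B = 32, C = 7) closes the budget to
  the digit.
* **3D lift** — every 2D convolution and pooling becomes 3D; clips of
  `N` consecutive frames are classified as one unit.
* **(2+1)D factorization** — each `k_t x k_h x k_w` convolution becomes
  a `1 x k_h x k_w` spatial convolution into `M` mid-channels, an
  intermediate BN (optional) and ReLU, then a `k_t x 1 x 1` temporal
  convolution.  `M = n_out` ("plain") gives 5,077,678 parameters, under
  half the 3D size; choosing
  `M = floor(k_t k_h k_w n_in n_out / (k_h k_w n_in + k_t n_out))`
  ("star") matches the 3D budget within 0.1%.

The published (2+1)D totals (5,094,381 and 11,081,431) are *not*
reproduced exactly: no mid-channel or bias convention we could derive
yields those two figures, while the same conventions reproduce all four
other rows exactly.  The audit therefore reports the derived counts and
treats closeness (1%) as the checkable property.

Two printed details are treated as slips rather than design: a stride of
"(0, 1, 1)" is undefined (all convolution strides are 1; pooling does
all downsampling), and the G-FLOP column depends on an unstated input
resolution and counting convention, so the audit prints its own estimate
(1 MAC = 2 FLOPs, convolutions only) without asserting equality.

### Shapes and pooling

Input resolution is a free parameter (the source work never states
one); the synthetic default is 64x64.  The 3D pooling schedule defaults
to `(1,2,2), (2,2,2), (2,2,2), (2,2,2)` with floor division, so an
`N = 10` clip passes 10 -> 10 -> 5 -> 2 -> 1 frames; an all-`(2,2,2)`
schedule would annihilate the temporal axis.  Configurations whose clip
length or image size collapses to zero at some pooling stage are
rejected with the offending stage named.

## The data pipeline

* **Clips** — within each maximal run of identically labelled frames,
  `floor(run/N)` non-overlapping `N`-frame clips are cut, anchored at
  the run start; remainder frames are dropped, and no clip crosses a
  label change.  The matched 2D dataset takes the central frame
  (`start + floor(N/2)`, an explicit convention for even `N`) of every
  clip, so both model families compete on identical label multisets.
* **Splits** — the test set is drawn only from patients whose exam has
  all five scans (`floor(test_frac * n_complete)` patients); remaining
  patients are shuffled per seed into train/validation with the train
  side floored at 80%.  The published example (413 patients -> 56 test,
  357 -> 285/72) pins down both floors.  Patients never straddle sets,
  and the test draw can be held fixed while train/validation reshuffle.
* **Sampling** — inverse class-frequency weights with replacement give
  every class an expected batch share of `1/K`.
* **Augmentation** — flips (p = 0.5 each), gamma in [0.7, 1.4], scale
  in [0.8, 1.2] about the center (center-crop when zooming in, zero-pad
  when zooming out), rotation in ±10 degrees with zero fill, bilinear
  interpolation, in that order.  Parameters are drawn once per clip and
  applied to every frame — per-frame draws would destroy exactly the
  temporal coherence the 3D models are meant to read.

## Training

Adam with weight decay 1e-4 (L2 added to the gradient, every trainable
tensor), initial learning rate 1e-5 (2D) or 1e-4 (3D/(2+1)D), batch 128
(2D) or 8 (3D), at most 200 epochs with early stopping on the
validation loss (patience 10, best weights restored — the restoration
is our choice; the source is silent) and a reduce-on-plateau schedule
whose own factor/patience are unpublished (defaults here: 0.5 and 5).
The loss is softmax cross-entropy (the head is softmax; the loss is
never named explicitly).  The three-fold hold-out keeps the test set
fixed and re-randomises train/validation with seeds {0, 1, 2}.

When a scan prior is supplied at training time, disallowed logits get a
finite additive penalty (-1e9) so the loss stays defined; at inference
the mask is `-Inf`, which provably cannot reduce accuracy as long as the
true class is always allowed.  Whether the original masked-training
experiment also masked at evaluation is unstated; we apply the same
prior at both stages.

### The numerical engine

No deep-learning runtime exists in the target environment, so the
executable network is an in-package engine: im2col + single-precision
GEMM convolutions (channels-major orientation, branch-free patch
extraction from a zero-padded buffer), max-pooling with stored argmax,
batch normalisation with biased batch statistics and running estimates
(momentum 0.1, eps 1e-5), He-initialised bias-free weights keyed to an
explicit seed, and Adam.  Forward/backward kernels are verified against
direct-loop oracles and finite differences in the test suite.  Single
precision bounds gradient agreement at roughly 1e-3 relative — ample
for training, and irrelevant to the (integer) parameter audits.

## The synthetic world

Real abdominal ultrasound data of this kind is private, so the package
ships a generator that reproduces the *statistical structure the method
relies on*, not ultrasound physics:

* multiplicative unit-mean gamma speckle (shape 4) over a low base
  echogenicity, bright anti-aliased ellipses for anatomy;
* five scans per exam, each an ordered landmark sequence with Other
  segments in between (40-frame segments, 200 frames per scan);
* class 3 ("Heart") pulsates (period 8 frames, amplitude 0.25, phase
  randomised per segment); class 6 ("Other") renders a *static twin* of
  the heart whose center, axes and frozen pulsation phase are drawn
  from the heart's own single-frame distribution.  Heart and Other are
  therefore indistinguishable in any single frame but trivially
  separable from a 10-frame clip — the designed mechanism behind the
  2D-vs-3D acceptance experiment.  Two generator details exist purely
  to keep that measurement honest: the per-segment random phase (a
  frame-locked phase would leave the central frames of a clip sampling
  only two discrete ellipse sizes, a residual single-frame cue), and a
  protocol that exposes Heart and Other in equal measure (10 segments
  each per exam), since a pooled-accuracy threshold on an unbalanced
  subset would grade majority share rather than temporal
  discrimination;
* the remaining classes get distinct static geometries with mild drift,
  and each scan's allowed-class set (always containing Other) doubles
  as the scan-prior table.

What a green test does **not** establish: anything about real tissue
texture, probe motion, class frequencies of clinical exams, or the
absolute accuracies published for the private dataset.  The synthetic
experiment checks the *mechanism* (temporal information separates
temporally-defined classes; priors help; budgets match), not the
numbers.

The desk-scale acceptance run uses base width 8 at 64x64, N = 10,
20 patients, and a deliberately scaled-down recipe — no augmentation,
learning rate 1e-3, 448 weighted draws per epoch, 2 epochs — sized so
the whole experiment fits a single-CPU budget (the 3D model already
reaches perfect validation accuracy within its first epoch).  The
thresholds (spatio-temporal >= 0.90, central-frame 2D <= 0.60 on the
Heart/Other subset) are fixed acceptance thresholds, not tuned quantities.

## Known limitations

* The engine is CPU-bound and single-threaded; canonical-size (B = 32)
  training is out of desk scope, only auditing is.
* Checkpoints are RDS files, not an interchange format.
* The generator's Other class is heart-like by design; a generator
  whose background never resembles a landmark would let a 2D model do
  better than chance on the subset task, and that is intentional here.
* Mixed-label clips in the protocol-style evaluation default to the
  central-frame label (majority is available); population (not sample)
  standard deviation is used for class-wise spread.
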