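---
title: "Auditing shortcut learning with inpainted counterfactuals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing shortcut learning with inpainted counterfactuals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dermoscopy archives used to train skin-cancer classifiers contain
non-diagnostic artefacts. The best-known case is the elliptical colour
calibration patch: in the widely used ISIC collection these patches appear in
roughly 46% of benign lesion images and in no malignant image. A classifier
trained on such data can reach high benchmark accuracy by learning
*patch ⇒ benign* — a shortcut (also called "Clever Hans" behaviour) — rather
than reading the lesion. The risk is asymmetric and clinically serious: a
malignant lesion photographed next to a calibration patch may be confidently
called benign.

`shortcutaudit` implements a model-agnostic audit of this failure mode. It
never inspects or modifies the classifier under test; it only feeds the
classifier carefully constructed counterfactual images and analyses the
paired prediction shifts. Because the intervention is on the *data*, the same
audit applies to a CNN, a gradient-boosted model, or the package's own
reference classifier.

## The audit procedure

Write $P(\text{mal}\mid x)$ for the classifier's malignant-class probability,
with $P(\text{ben}\mid x) = 1 - P(\text{mal}\mid x)$.

**Removal audit.** On the test-set benign images that contain a patch (set
$A$), the patch is segmented, the mask dilated, and the region replaced by
inpainted skin, giving $x'_{-patch}$. The statistic

$$\mathrm{MAD}_{\text{ben}\setminus patch} \;=\;
\frac{1}{|A|}\sum_{x\in A}\bigl|P(\text{ben}\mid x'_{-patch}) -
P(\text{ben}\mid x)\bigr|$$

measures how much the true-class probability depends on the patch.

**Insertion audit.** On the malignant test images without patches (set $B$),
a patch template extracted from a benign image is composited at a random
boundary location disjoint from the lesion, giving $x'_{+patch}$, and the
analogous $\mathrm{MAD}_{\text{mal}+patch}$ uses $P(\text{mal}\mid\cdot)$.

Alongside each MAD the audit reports the signed-deviation summary: the
fraction of images whose true-class probability decreased (%P↓), the mean
magnitude of those negative deviations (MND — undefined, never zero, when no
image decreased), and the flip rate: the fraction of initially correctly
classified images whose predicted class crosses the decision boundary after
the alteration. Classification uses the rule *malignant iff*
$P(\text{mal}\mid x) \ge t$ with $t = 0.4$ by default; the boundary tie goes
to malignant because the threshold exists to favour sensitivity. A variant of
the flip rate over *all* pairs (any crossing, either direction) is always
computed alongside, since both denominators are defensible readings of the
statistic; the restricted one is the default because it directly answers
"how many correct diagnoses does the artefact destroy".

**Validity check.** Counterfactuals are only meaningful if inpainting itself
is uninformative to the classifier. On patch-free images the audit inpaints
*random* elliptical regions drawn from the same geometry prior as real
patches and checks that (i) SSIM between original and inpainted images stays
near 1 and (ii) the distribution of
$\Delta P = P(\text{mal}\mid\text{inpainted}) - P(\text{mal}\mid\text{orig})$
centres on zero. Images with $|\Delta P| > 0.2$ are flagged for inspection,
never dropped: they are where lesions got partially covered or the model is
fragile, and both are findings.

**Footprint control.** A drop after insertion could in principle come from
the patch *covering* informative pixels rather than from the patch itself.
The control inpaints the exact footprint the patch would have covered —
without compositing the patch — and compares the $|\Delta P|$ distributions.

**Correction.** The de-biasing step segments and inpaints every detected
patch in the *training* set and retrains the same architecture on the
altered data. The full experiment then repeats all audits for the vanilla
and retrained classifiers and computes the per-subgroup Pearson correlation
of their test predictions (malignant / benign-without-patch /
benign-with-patch). A low correlation confined to the benign-with-patch
subgroup is the signature of a removed shortcut: those are exactly the
images the vanilla model scored with the artefact.

## Patch segmentation

Detection follows the superpixel + colour-distance recipe. The image is
partitioned into SLIC superpixels (deterministic grid initialisation,
windowed Lloyd iterations; implemented in C++ since no installed R package
provides SLIC). A robust skin tone is estimated as the per-channel *median*
RGB over the image — the median rather than the mean so a large dark lesion
cannot drag the estimate. Each superpixel's mean colour is compared with the
skin tone by the Euclidean distance over concatenated coordinates
$(r, g, b, \cos 2\pi h, \sin 2\pi h, s, v)$; hue enters through its cosine
and sine so red and magenta are near each other, not at opposite ends of a
line. Superpixels above the distance threshold form the mask; connected
regions smaller than `min_region_area` are dropped.

Tunables and defaults (at the 128 px working scale):

| parameter | default | why |
|---|---|---|
| `n_superpixels` | 200 | superpixel pitch ≈ 9 px, small enough to trace patch borders |
| `compactness` | 10 | conventional value with colour on a 0–255 scale |
| `colour_distance_threshold` | 1.0 | sits between the largest lesion-vs-skin distances (≈ 0.8) and the smallest patch-vs-skin distances (≈ 1.3) in the synthetic model |
| `min_region_area` | 25 px | rejects single-superpixel colour flukes |
| `dilation_size` | 5 (128 px), 9 (224 px) | see below |

The mask is dilated with an elliptical structuring element before
inpainting so that patch borders missed by the segmentation cannot seed a
"repair" of the patch. The conventional element is 9×9 pixels at the
224×224 resolution standard; `seg_config()` scales the diameter
proportionally with the working resolution (odd-rounded, minimum 3), because
a fixed 4-pixel dilation radius at half the resolution would inflate a
typical patch mask by 40–80% in area and make the dilated mask a poor
estimate of the patch. Externally supplied masks (e.g. re-used from another
study) follow the same path: they are dilated and used verbatim.

## Inpainting

The reference backend is classical harmonic inpainting: masked pixels solve
the discrete Laplace equation with Dirichlet boundary values from the
unmasked 4-neighbourhood, computed exactly per channel with one sparse SPD
solve. This is the smoothest interpolation of the surrounding skin — by
construction it adds no structure of its own, which is precisely the
"uninformative fill" property the audit needs, and the validity check
verifies that property empirically rather than assuming it. Learned
inpainting models plug in through `register_inpaint_backend()`; every call
through `inpaint()` re-verifies the backend contract (pixels outside the
mask bit-exactly unchanged, filled pixels in [0, 1]).

SSIM uses the standard Gaussian-weighted 11×11 window, σ = 1.5,
K₁ = 0.01, K₂ = 0.03 on a unit dynamic range, channel-averaged; the
half-window border is excluded from the mean so no padding convention leaks
into the score.

## The synthetic data generator

Real ISIC images cannot be bundled or downloaded here, so the generator
produces the *structure* of the confound with ground truth: textured skin
(base RGB (0.80, 0.60, 0.52), low-frequency multiplicative field, Gaussian
pixel noise sd 0.02); one irregular pigmented lesion per image whose
darkness ~ N(contrast, 0.08) and border raggedness both derive from a
per-class contrast parameter (0.35 benign, 0.55 malignant), giving the
classifier a legitimate signal with deliberate class overlap; and, with
probability 0.46 for benign images only, one saturated elliptical patch
(hue from {blue, green, cyan, magenta}, s, v ~ U(0.75, 0.95); semi-axes
U(0.10, 0.25) of the image side; centre in the outer quarter of the frame,
placed disjoint from the lesion, with a bounded retry and an explicit flag
when no disjoint placement exists). The contrast gap was fixed so that a
classifier trained on patch-free data separates the classes with held-out
sensitivity and specificity above 0.8 at the balanced 0.5 operating point —
0.4 is a deployment choice that deliberately trades specificity for
sensitivity, so the generator's separability property is stated at 0.5 —
while enough overlap remains that a confounded classifier has a real
incentive to use the patch.

What the generator does *not* emulate: hair, rulers, gel bubbles and
vignettes (other known dermoscopy artefacts), realistic pigment-network
texture, class imbalance, and patch colour distributions calibrated to the
archive (unreported there). Passing audits on this generator therefore show
that the machinery — segmentation, counterfactual construction, statistics,
de-biasing — behaves correctly under a known confound; they do not certify
performance on real dermoscopy images, where segmentation difficulty and
classifier behaviour are both harsher.

## The reference classifier

The audit needs a classifier that can genuinely *acquire* the shortcut and
be cured of it, at desk scale. The reference model extracts 27 engineered
features and fits a ridge-penalised logistic regression (deterministic,
seconds on a CPU). The features are split by design:

* legitimate signal, measured robustly: per-channel quartiles, low
  quantiles of the value channel (pigment darkness), the pigmented-area
  share (saturated pixels in the red/orange hue band), mean darkness of the
  pigmented region, a perimeter/√area border-irregularity index, and
  gradient statistics;
* artefact signal: area shares of saturated pixels in the non-pigment hue
  bands and of very-high-saturation (s > 0.75) pixels — lesion pigment never
  reaches those hues or that saturation, so these features respond to
  calibration patches only.

Two numerical choices matter. First, the ridge is applied *without* internal
standardisation: after de-biasing, the artefact features are near-constant
in the training data, and standardising by a vanishing standard deviation
turns them into numerically explosive columns with arbitrary-sign weights.
Penalising on the natural scale keeps a constant feature at exactly zero
weight. Second, because area-share features live on a [0, 0.2] scale while
quantile features live on [0, 1], area shares are multiplied by a common
constant (`AREA_SCALE = 6`) so the penalty treats both groups comparably.
That constant also sets how "cheap" the shortcut is for the optimiser; it
was calibrated once so the confounded reference model's reliance magnitudes
fall in the regime reported for full-scale transfer-learned CNNs audited
with this method (removal MAD ≈ 0.2–0.3, insertion flip rate ≈ 60–70%), and
is not adjusted per experiment.

`TrainConfig` records the conventional SGD settings of full-scale
dermoscopy classifiers (10 epochs, learning rate 1e-5, momentum 0.9) for
external adapters; the built-in convex fit has no use for a step size. The
decision threshold is stored in the config but applied only at metric time,
never during training. Optional inverse-frequency class weighting is
available and off by default. External models join the audit by implementing
a `predict_proba()` method; `check_classifier_contract()` verifies the
probability-sum, determinism, batch-consistency and empty-batch behaviours
the audits rely on.

## Degenerate inputs and tie-breaks

* `estimate_skin_tone` refuses an exclusion mask covering every pixel.
* `segment_patches` returns an all-false mask when nothing exceeds the
  threshold; a cheap per-pixel distance count skips the superpixel stage
  entirely when fewer pixels than `min_region_area` could possibly qualify.
* `inpaint` refuses a mask covering the whole image (no boundary data).
* MND is reported as undefined (`NA`), never 0, when no deviation is
  negative; the restricted flip rate errors when no pair was initially
  correct; Pearson fidelity is `NA` and flagged for subgroups smaller than
  3 or with zero variance.
* Patch placement (generation and insertion) retries up to 50 times for a
  lesion-disjoint position; generation then emits the image without a patch
  and flags it, insertion raises an error naming the image so the caller
  can log the exclusion — sample conservation between report and exclusion
  log is asserted in the tests.
* `p = threshold` classifies as malignant (sensitivity-favouring).
* All randomness flows through explicit seeds; the experiment driver derives
  an independent deterministic seed per stage from one master seed, so any
  stage can be reproduced in isolation.

## Problem sizes

The bundled experiments run at sizes chosen for a single CPU: 128×128
images; 2,000 images (1,600 train / 400 test) for the end-to-end de-bias
experiment; 200 images for the segmentation-recovery and validity studies;
the full experiment completes in a few minutes. The same code paths accept
224×224 images, where the segmentation defaults reduce to the conventional
9×9 dilation element.

## Known limitations

* Harmonic fill leaves a locally smooth (texture-free) region. The SSIM
  validity numbers quantify this, and the de-biased training set therefore
  carries a mild "smoothness" cue where patches used to be — the same risk
  a learned inpainter has of being detectable, discussed openly here
  because the per-subgroup fidelity analysis would surface it if a
  classifier exploited it.
* The colour-distance threshold is validated on the synthetic palette only;
  real archives need the threshold checked against their patch colours.
* One unscaled template is inserted per image; template scaling or
  photometric adaptation is out of scope.
* The audit quantifies reliance on *segmentable* artefacts; a bias that
  cannot be masked cannot be audited this way.
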