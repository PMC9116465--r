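---
title: "Perceptual quality assessment for confocal endoscopy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual quality assessment for confocal endoscopy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceiqa)
```

## The problem

Fiber-bundle confocal endoscopes image mucosal tissue at micron resolution
through a circular effective field of view surrounded by black pixels. The
images are frequently degraded — defocus and motion blur, detector noise,
contrast loss — and an examination yields far more frames than a clinician
can triage. Because no undistorted reference frame exists, quality must be
predicted *blind*, from the distorted image alone, on the same 1–5
mean-opinion-score (MOS) scale that human raters use.

`ceiqa` predicts that score from perceptual texture statistics. The design
premise is Weber's law: the human visual system responds to *relative*
intensity change, ΔI/I, not absolute change. Every component of the
descriptor is built around that ratio.

## The descriptor

For a pixel with intensity $x_c$ and its $P$ circular neighbors $x_i$:

**Differential excitation (DE).**
$$\mathrm{DE} = \arctan\!\Big(\sum_{i=1}^{P}\frac{x_i - x_c}{x_c}\Big)
  \in [-\pi/2, \pi/2].$$
The arctangent compresses extreme ratios and keeps the map bounded. DE is
invariant to multiplicative intensity scaling. Empirically (and this is
testable on the synthetic phantoms, see `test-pipeline.R`), blur pulls DE
mass toward zero while structured tissue spreads it out — so the
*distribution* of |DE| carries quality information.

**Rotation-invariant uniform LBP.** Bits $s(x_i - x_c \ge 0)$ around the
circle; patterns with at most two bitwise transitions are coded by their
number of set bits (codes $0\ldots P$), all others share code $P{+}1$ —
10 codes at $P = 8$. Codes are invariant to rotation and to additive
intensity shifts, complementing DE (which keeps intensity but ignores
pattern).

**DE–LBP joint histogram.** $H(m,n)$, the fraction of pixels with LBP code
$m$ and $|\mathrm{DE}|$ in bin $n$ of $N$ equal-width bins over
$[0, \pi/2]$; $10 \times 10$ flattened code-major into 100 features.

**Weber-thresholded LTP (WB-LTP).** A ternary code per neighbor,
$+1$ if $(x_i - x_c)/x_c > t$, $-1$ if $< -t$, else $0$, with the adaptive
threshold
$$t = \tan(\overline{|\mathrm{DE}|})/256$$
mapping the image's own mean variation intensity back to a ΔI/I ratio. The
ternary map splits into binary `up`/`low` channels (powers-of-two
weighting, values 0–255) and a magnitude channel $\sqrt{up^2 + low^2}$.
Each channel contributes a 15-bin histogram, plus one Shannon entropy per
channel over its discrete levels: 45 + 3 = 48 features.

**Multi-scale assembly.** Features are extracted on the square inscribed in
the valid circle (side $\lfloor r\sqrt2 \rfloor$; the black annulus would
otherwise contaminate every histogram), at the original scale and two
successive 2×2 mean-pooling downsamplings. The Weber threshold is computed
once at the original scale and halved per scale, $t_s = t/2^s$, matching
the halving of spatial frequency content. Total:
$3 \times (100 + 48) = 444$ features.

```{r}
feature_length(ceiqa_config())
```

## Decisions where the design was open

Several conventions are not forced by the formulas; the package fixes them
as follows.

- **Absolute DE.** Both the joint-histogram axis and the mean inside the
  threshold formula use $|\mathrm{DE}|$. A signed mean would let positive
  and negative variation cancel and could produce a negative threshold;
  the absolute value keeps $t \ge 0$ and matches how DE maps are usually
  visualized.
- **+1 intensity offset.** Applied once to the whole cropped image before
  any descriptor. It removes the zero-center instability of both the DE
  ratio and the ternary ratio test with a bias of at most 1/256 of the
  intensity range. The low-level functions (`de_map`, `wb_ltp`) operate on
  the values they are given and reject zero centers, so the offset is
  explicit, not hidden.
- **Neighborhood sampling.** At the default $R = 1$, $P = 8$ the 8 grid
  neighbors are used directly; other $(R, P)$ use bilinear interpolation at
  angles $2\pi i/P$ (standard LBP practice). Descriptors are computed only
  where the full neighborhood exists — maps shrink by $\lceil R\rceil$ per
  side; padding would fabricate texture.
- **10 code bins.** Uniform coding emits codes $0\ldots P{+}1$, i.e.
  $P{+}2 = 10$ values at $P=8$; only this yields the documented
  $10 \times 10 = 100$ joint histogram.
- **Histogram ranges.** `up`/`low` are binned over their full theoretical
  range $[0, 255]$, magnitude over $[0, 255\sqrt2]$ — parameter-free and
  comparable across images. All histograms are normalized per image (the
  joint histogram likewise), so features are image-size independent.
- **Ties.** A relative contrast exactly equal to $t$ takes the ternary
  code 0 (the "within threshold" branch). Spearman correlation uses
  midranks.
- **Entropy discretization.** `up`/`low` entropies use the raw integer
  codes; the magnitude channel is rounded to the nearest integer first.
  Entropy is 0 exactly for a constant channel and at most
  $\log_2(\text{levels})$.

## The quality model

An ε-SVR with radial-basis kernel ($\varepsilon = 0.1$) on features min-max
scaled to $[-1, 1]$. Scaling is learned from the training rows only — the
test suite checks that leaking held-out rows into the scaling measurably
changes predictions. $(C, \gamma)$ are selected by inner $k$-fold
cross-validation maximizing mean validation SROCC (the protocol's headline
criterion; selecting on MSE can favor a compressed score range). The
canonical grid is $C \in 2^{-5}\ldots2^{15}$,
$\gamma \in 2^{-15}\ldots2^{3}$ in $2^2$ steps with $k = 5$;
`ceiqa_grid_coarse()` subsamples it in $2^4$ steps with $k = 3$ for
protocols that refit hundreds of models. Selection is deterministic given
data, grid, and seed (ties break toward the first grid cell).

## The evaluation protocol

`repeated_split_eval()` draws seeded random splits — training size
$\lfloor 0.8 n\rfloor$, the remainder held out (642 images would give
513/129) — refits the full model per repeat, and reports median and SD of
SROCC, PLCC, and RMSE. PLCC and RMSE are computed after the five-parameter
logistic remapping
$$f(x) = \beta_1\big(\tfrac12 - \tfrac{1}{1+e^{\beta_2(x-\beta_3)}}\big)
  + \beta_4 x + \beta_5,$$
which absorbs any monotone nonlinearity (identity and affine maps are
family members with $\beta_1 = 0$). The fit is Levenberg–Marquardt on the
raw residuals, initialized from a preliminary linear fit with
$\beta_1 = \mathrm{range}(mos)\cdot\mathrm{sign}(\rho)$,
$\beta_2 = 1/\mathrm{sd}(pred)$, $\beta_3 = \overline{pred}$; the logistic
is evaluated through `plogis` so large $\beta_2$ cannot overflow. On noisy
near-linear data the $\beta_1$/$\beta_4$ trade-off direction is flat and
the optimizer can hit its iteration cap; the best-found curve (never worse
than the linear baseline, since descent is monotone) is used and the
convergence flag records the cap. Only a failed or non-finite fit falls
back to the identity mapping, with a warning.

Method comparison uses the corrected resampled paired t-test,
$$t = \frac{\bar d}{\sqrt{\hat\sigma^2_d\,(1/K + n_{test}/n_{train})}},$$
two-sided at 95% confidence with $K-1$ degrees of freedom: the
$n_{test}/n_{train}$ term corrects the anticonservative variance of
overlapping resampled training sets. `significance_matrix()` assembles the
antisymmetric $\{1, 0, -1\}$ decision matrix over methods evaluated on
identical split sequences.

## The synthetic benchmark

No public confocal-endoscopy quality dataset with MOS labels exists, so the
package generates one. `generate_phantom()` renders soft-edged elliptical
blobs (random position, size, orientation, mostly bright on a dim
background) plus a fine smoothed-noise grain inside a circular FOV — enough
structure at all scales for the descriptors to be non-trivial.
`apply_distortion()` degrades it with defocus blur
($\sigma = 3s$ px), motion blur (length $1 + 14s$ px, random angle),
Gaussian noise (SD $30s$ gray levels), contrast compression (gain
$1 - 0.8s$), or a sequential mix, each parameter monotone in severity
$s \in [0,1]$ and $s = 0$ the exact identity. Pseudo-MOS emulates an
8-rater study: true quality $5 - 4s$, per-rater Gaussian noise such that
the rater mean has SD 0.25, clipped to $[1, 5]$; an optional filter drops
items whose simulated rater SD exceeds 1.5, mirroring how unreliable
subjective scores are screened.

What passing on this benchmark shows: that the descriptor separates graded
blur/noise/contrast degradations of textured circular-FOV images and that
the full protocol machinery is correct. What it does **not** show:
performance on real tissue (fiber-bundle honeycomb artifacts, optical
point-spread functions, tissue-type content variation, and authentic mixed
distortions are all absent), so absolute correlation values here are not
comparable to values measured on instrument data.

## Problem sizes and reproducibility

The packaged study conditions are 40 phantoms × 5 severities (200 images,
one distortion family per phantom), 50 evaluation repeats with the coarse
grid, and a 20%-of-phantoms holdout for the severity-ladder ranking check —
sizes at which the complete pipeline recomputes in a few minutes on one
core while keeping the split distribution informative. Every stochastic
step (phantom rendering, distortion, rater noise, splits, folds) derives
from a single seed; `scripts/acceptance.R` re-runs everything from scratch
and writes the measured quantities as JSON.

## Known limitations

- The phantom texture is a statistical stand-in, not a tissue model; no
  claim of biological realism.
- The corrected resampled t-test is itself approximate (the correction is a
  heuristic for split overlap); decisions near the threshold should not be
  over-read.
- Features are content-sensitive: images of intrinsically low-variance
  tissue can score lower than their distortion level warrants. This is a
  property of the descriptor family, not of the implementation.
- JPEG/TIFF support depends on the optional `jpeg`/`tiff` packages; PNG is
  always available.
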