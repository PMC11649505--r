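---
title: "Methods: hybrid CNN-transformer segmentation of microscopic hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid CNN-transformer segmentation of microscopic hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperseg)
```

## The problem

Microscopic hyperspectral imaging (MHSI) records a pathology slide as a cube
`[H, W, B]` with tens of narrow spectral bands per pixel — here 40 bands
spanning 450–700 nm at 6.25 nm resolution. The biochemical state of tissue
modulates the per-pixel spectrum, so the band axis carries diagnostic signal
that an RGB image does not. The task this package addresses is binary
semantic segmentation of such cubes: labelling each pixel as lesion
(e.g. precancerous gastric mucosa) or background.

Pure CNN encoders capture local texture but not long-range context; pure
transformers tokenize at one fixed patch scale and usually attend only over
spatial positions. The network implemented here combines both and adds three
specific mechanisms:

1. **Multi-scale token division (MSTD)** — tokenize the CNN feature map at
   *two* patch scales and fuse the token sets with a bounded gating function.
2. **Spatial-channel fusion transformer (SCFormer)** — run multi-head
   attention over token positions *and* over feature channels in parallel,
   connect channel attention densely across blocks, and fuse the two streams
   with a cross-attention gate.
3. **A deformable-convolution decoder** — decode with modulated deformable
   3×3 convolutions whose sampling grid adapts per position.

## Model

### Encoder stem

A three-stage residual CNN (strides 2/2/2, widths `cnn_widths`) maps the
`[H, W, k]` input (the PCA-reduced cube, `k = 3` by default) to feature maps
at 1/2, 1/4 and 1/8 resolution. The 1/2, 1/4 and 1/8 maps are kept as skip
connections for the decoder. Each stage is `conv3×3(stride 2) → norm → ReLU
→ conv3×3 → norm` with a 1×1 strided shortcut. Normalization is per-channel
over the spatial extent (instance normalization): with batch size 4 and a
CPU training loop, batch statistics would be noisy, and instance norm keeps
every forward pass independent of batch composition — which is also what
makes the seeded-determinism contract simple to honour.

### Multi-scale token division

Let `Z` be the 1/8-resolution feature map with even side lengths. The fine
tokenizer is an `a×a`/stride-`a` patch convolution on `Z`; the coarse
tokenizer is a `b×b`/stride-`b` patch convolution applied to a mirror-padded
copy of `Z` whose side is scaled by `b/a`. For the default pair `(2,4)` the
padding doubles the map (H/2 rows and W/2 columns reflected on each side,
edge sample not duplicated), and both tokenizers produce the same
`(H/a)×(W/a)` grid — equal token counts is the precondition for fusion.

Each token set (`D` channels) is split into channel halves
`Z1 → (Z1[0], Z1[1])`, `Z2 → (Z2[0], Z2[1])`, and fused with the
`A(x) = tanh(x) + 1` gate:

```
f0 = Z1[1] + Z2[0]
F1 = A(f0 ⊙ Z1[0]) + Z1[0]
F2 = A(f0 ⊙ Z2[1]) + Z2[1]
F0 = A(f0 ⊙ F1 ⊙ F2) + f0
out = [F0 | F1 + F2]
```

`A(·)` maps any real value into (0, 2): a gated product can suppress a
feature (towards 0), pass it (near 1) or amplify it (towards 2), while the
residual terms preserve the ungated signal. Under this reading every channel
half is used exactly once, which is also what the anti-dead-branch test
verifies: after one backward pass, every tokenizer weight receives gradient.

Two design points were genuinely open and are fixed as follows:

* **Which half enters the first gate.** The surrounding prose and the
  equations of the source description disagree; the equations (gate on
  `Z1[0]`) are followed, because under the prose reading `Z1[0]` would never
  be used at all.
* **Generalized padding.** Only the doubling pair `(2,4)` has a stated
  padding rule. For a pair `(a,b)` the map is reflect-padded to `(b/a)·H`,
  which reduces to the stated `2H×2W` rule at `(2,4)` and keeps the two
  grids equal for `(2,3)`, `(2,5)` and `(3,5)`. Geometries that would need
  fractional padding are rejected at build time with an explicit error.

### Spatial-channel fusion transformer

Tokens (plus a learned positional embedding, added once before block 1)
pass through `n_blocks = 3` SCFormer blocks. Block `j` computes:

* **MCA** (multi-head channel attention): queries and keys derive from
  `x + d(z)`, where `d(z)` is the *dense connection* — the sum of all
  previous block outputs — passed through a learned projection; values
  derive from `x` alone. Attention is *transposed*: per head, the
  similarity matrix is `d_k × d_k` between feature channels, independent of
  the token count. This is the established channel-attention-transformer
  construction, chosen because "channel attention" is not mechanically
  defined in the source description.
* **MSA** (multi-head spatial attention): standard token-axis self-attention
  on `x`, with an `N × N` per-head similarity. The dense connection feeds
  MCA only, following the equations.
* **CAF** (cross-attention fusion): `A(F1⊙F2 + F1⊙F_prev + F2⊙F_prev)` with
  `F1` the MCA stream, `F2` the MSA stream and `F_prev` the previous block's
  output (for block 1, the block-stack input, i.e. the MSTD output — the
  source leaves this case undefined). The three pairwise products emphasize
  features the streams agree on, which is the stated mechanism for
  suppressing the semantic gap between spatial and channel features.
* **MLP**: linear(D→4D) → GELU → dropout → linear(→D) → dropout, applied
  under a residual connection around the CAF output.

The phrase "LN represents the fully connected layer" in the source is
unusual; it is implemented as layer normalization followed by a learned
linear projection (the standard pre-norm transformer reading, consistent
with the hybrid-baseline design the network adopts), with
`prenorm = FALSE` switching to the literal pure-linear reading. Block 1 owns
no dense projection parameters at all — it has no predecessors, and
parameters that can never receive gradient would be dead weight.

### Decoder

Token vectors are reshaped to a map and climbed back to full resolution by
four up-blocks. Each block bilinearly upsamples to the resolution of its
skip connection (2× when there is none), concatenates the skip, and applies
a modulated deformable 3×3 convolution

```
y(p) = Σ_k  w_k · x(p + p_k + Δp_k(p)) · Δm_k(p)
```

with bilinear sampling at the displaced positions and zero contribution
outside the image. A zero-initialized standard convolution predicts the
`2K` offsets and `K` modulation logits per position; the logits pass through
a sigmoid and are rescaled by 2 (`modulation_rescale = TRUE`), so an
untrained predictor yields offsets 0 and modulation exactly 1 — the decoder
starts at the plain-convolution limit, which stabilizes early training. A
1×1 convolution produces the class logits at the input resolution.

Skip-driven upsampling (rather than fixed 2×) is what lets non-doubling
token grids — e.g. the 1/24-resolution grid of the `(3,5)` pair — decode to
the exact input size; for the default `(2,4)` pair it reduces to the
standard doubling cascade.

## Loss and metrics

Training minimizes `0.7·CE + 0.3·(1/C)·Σ_c Dice_c`: pixel-mean
cross-entropy plus the class-averaged soft Dice loss
`1 − (2Σp_c g_c + ε)/(Σp_c + Σg_c + ε)` with `ε = 1e-5` (guards 0/0 on
empty classes; the source states no value). Dice is computed on softmax
probabilities for differentiability; evaluation uses argmax masks.

Evaluation reports overall accuracy, sensitivity, IoU and Dice similarity
of the lesion class from pixel confusion counts pooled over the whole test
set (micro aggregation; the fold summary averages the per-fold metrics —
the source does not state its aggregation). Zero-denominator ratios report
1 when the condition is vacuously satisfied. `DSC = 2·IoU/(1+IoU)` holds as
an exact identity and is asserted in the tests.

## Training protocol

SGD with learning rate 0.01, momentum 0.9, weight decay 1e-6, batch size 4,
constant learning rate (no schedule is named in the source; a constant
default keeps the protocol minimal). 45 epochs is the default profile
(60 for the second dataset profile). The checkpoint kept is the epoch with
the lowest *training* loss — no inner validation split is described, so
model selection uses the epoch-mean training loss. Five-fold
cross-validation assigns items by seeded shuffle + round-robin (fold sizes
differ by at most 1), trains on 4/5 and evaluates the held-out fifth.

Determinism contract: a fixed seed reproduces weight initialization, data
shuffling, dropout masks and therefore the entire loss trajectory exactly,
on one device. Cross-device bitwise equality is not promised.

## PCA preprocessing

Pathology MHSI bands are strongly correlated, so the cube is compressed
along the band axis before entering the network. `pca_reduce` treats pixels
as observations, mean-centers, projects onto the top-`k` principal axes,
and min-max scales each component plane to [0, 1] so the CNN stem sees a
fixed input range (the source is silent on post-PCA normalization). The
fit is per image by default — component visualizations in the source are
per-image — with a `basis` argument for a dataset-wide fit. Axis signs are
fixed by making each axis' largest-magnitude loading positive, so results
are deterministic and comparable to the eigendecomposition oracle used in
the tests. The default `k = 3` sits at the reported
rise-then-fall optimum of the band-count sweep (1–5).

## Synthetic data: what it emulates and what it does not

No public MHSI dataset accompanies the source (the two gastric datasets are
available only on request), so the package ships a seeded generator that
reproduces the *statistical* structure every module depends on:

* **Spectral grid**: 40 bands, 450–700 nm, 6.25 nm steps — the stated
  acquisition grid, and the default the acceptance check verifies.
* **Low-rank spectra**: each pixel is a convex mixture of `n_endmembers = 3`
  smooth positive endmember curves (baseline plus ≤ 3 Gaussian bumps). With
  zero noise the cube lies exactly in the endmember span, so PCA with
  `k = n_endmembers` explains > 99.9% of variance — the property that
  justifies PCA preprocessing.
* **Inter-band correlation**: a smooth multiplicative brightness field,
  shared by all bands, models illumination/absorbance variation; it is the
  dominant source of the high band-to-band correlation seen in real
  pathology cubes (mean |r| > 0.8 at the defaults) and — being a scalar per
  pixel — preserves the endmember span.
* **Lesion geometry**: masks are Gaussian random fields (correlation length
  `lesion_smoothness`) thresholded at the quantile that yields the target
  foreground fraction, giving contiguous irregular blobs. Thresholded
  smoothed noise was chosen over parametric ellipses because lesion margins
  are irregular; the fraction default 0.3 is a choice, not a reported
  value (the source reports no class fractions), and is config-exposed.
* **Class contrast**: foreground and background use distinct Dirichlet-drawn
  mixing weights, blended by a `contrast` scalar (default 0.8 — separable
  but overlapping; `contrast = 1` gives the "easy" regime the overfit
  check uses). A small smooth jitter of the per-pixel weights keeps classes
  from being two exact spectra while staying inside the endmember span.
* **Noise**: additive i.i.d. Gaussian (`noise_sigma = 0.01`); shot noise
  and detector artefacts are out of scope.

The generator targets these statistics, **not** histological appearance. A
green test therefore establishes that the implementation is faithful and
trainable, not that it reaches any particular accuracy on real gastric
tissue — reproducing the published accuracy tables would require the
private datasets and GPU-scale training, which is explicitly out of scope.

## The frozen reference configuration

The published description fixes the architecture's shape but not the
encoder widths or embed dimension; the only published capacity figure is
the total budget of 34.59M trainable parameters. The shipped default —
stage widths (64, 128, 256), embed dimension 720 with 8 heads, decoder
widths (236, 128, 64, 24), 512×512 input, scale pair (2,4) — was calibrated
once against that budget (34,589,710 parameters, i.e. 34.59M) and then
frozen; `scripts/acceptance.R` rebuilds it and recounts at run time. Counts
are exact sums over every trainable scalar, so the check is deterministic.

## Numerical choices

* All network arithmetic runs in double precision on a small reverse-mode
  autodiff tape written for this package (the environment provides no R
  deep-learning stack). Every hand-derived vector-Jacobian product —
  convolution, reflection padding, bilinear resampling, layer/instance
  norm, softmax attention, the token-fusion gate, the deformable
  convolution (gradients w.r.t. input, weights, offsets and modulation) and
  the fused compound loss — is verified against central-difference numerical
  gradients in the test suite.
* Bilinear sampling uses the align-corners-false convention; out-of-bounds
  samples contribute zero (both unstated in the source).
* Reflection padding never duplicates the edge sample and supports per-side
  amounts up to `H − 1` (single reflection), which covers every supported
  scale pair; larger requests fail loudly.
* Softmax rows are max-shifted before exponentiation; cross-entropy clamps
  probabilities at 1e-300 before the log.
* Token grids are flattened in R's native column-major order everywhere;
  this is pure bookkeeping with no observable effect on the math.
* Strided convolutions use floor semantics for the output size, matching
  the conventions of mainstream deep-learning frameworks.

## Known limitations

* CPU-only and single-image batches internally: practical for the test
  scale (64×64 inputs, thin widths), not for 512×512 GPU-scale training.
* Exactly two token scales; the source itself notes the two-scale limit.
* The transformer's positional embedding ties a built model to its
  configured input size.
* TIFF support is a minimal baseline codec (uncompressed, little-endian,
  grayscale pages); ENVI covers float/int interleaves BSQ/BIL/BIP; masks
  use PGM rather than PNG (no PNG codec is available in the environment).
* Figure-only details of the source (exact norm placement inside a block)
  cannot be confirmed from text; the standard pre-norm reading is used and
  the alternatives are config-switchable where they matter.
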