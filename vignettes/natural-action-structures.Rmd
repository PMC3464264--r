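---
title: "Natural action structures: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Natural action structures: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nasrec)
```

## The model

A *natural action structure* (NAS) is an equivalence class of multi-scale
spatiotemporal patch sequences: every interest point of a video contributes a
triple of circular patch sequences at three coupled scales (13×13 pixels over
11 frames, 25×25 over 21, 49×49 over 31), and two triples belong to the same
NAS when their three per-scale feature vectors fall into the same *structural
cluster* at every scale. Actions are then represented as bags (or spatial
grids) of NAS occurrences, which feed either a one-vs-rest SVM with the
1−χ² histogram kernel or per-action LDA topic models.

The pipeline has five stages.

1. **Interest detection.** The cuboid response
   $R = (V * g * h_{ev})^2 + (V * g * h_{od})^2$, where $g$ is a 2-D spatial
   Gaussian (σ = 2 px) and $h_{ev}, h_{od}$ a temporal quadrature pair of
   1-D Gabor filters (τ = 3 frames, carrier ω = 4/τ cycles/frame). Interest
   points are strict local maxima of $R$. Both temporal filters are
   mean-subtracted so a temporally constant video has exactly zero response:
   the detector marks motion, never static texture.
2. **Patch sampling.** At each point, the three coupled-scale blocks are
   cropped (middle frames aligned at the point's frame), reduced to a common
   13×13×11 grid by centred strided sampling — for the middle scale this is
   precisely the even-indexed sub-lattice counted from the centre; strides
   are (1, 2, 4) spatially and (1, 2, 3) temporally — masked to a centred
   digital disc of 129 pixels, flattened frame-major in a frozen row-major
   in-mask order, and mean-subtracted. All scales give vectors of the same
   length 129 × 11 = 1419, so one ICA routine serves all scales.
3. **IC bank.** Per scale, PCA whitening to `n_ic` dimensions followed by
   symmetric fixed-point ICA (logcosh contrast) yields unit-norm
   spatiotemporal filters. Each IC's highest-energy frame is fitted with a
   2-D Gabor (7 parameters; amplitude solved in closed form), the parameters
   canonicalised (orientation in [0, π), phase in [0, 2π), σx ≥ σy; the
   envelope location is left unconverted), and the ICs are K-means-clustered
   on the 6-vector (x₀, y₀, σx, σy, θ, φ) with plain Euclidean distance. The
   carrier frequency is fitted — a Gabor is ill-defined without it — but
   excluded from clustering.
4. **Codebook.** Each patch vector `P` maps to per-IC-cluster RMS features
   $a_i = \sqrt{\tfrac1{m_i}\sum_{j \in i}(P\!\cdot\!A_j)^2}$; per-scale
   K-means over these feature vectors defines the structural clusters, and
   the NAS index of a patch triple is the triple of nearest-centroid indices.
   Discriminative NASs are selected by (i) dropping NASs occurring ≤ Mc
   times in training and (ii) for every ordered class pair, ranking by the
   difference of mean per-video relative frequencies and keeping the top Nc.
5. **Classification.** Grid-pooled NAS histograms (n-m-k equal-width bands,
   vertical first) under a one-vs-rest SVM with kernel
   $K(x,y) = 1 - \tfrac12\sum_i (x_i-y_i)^2/(x_i+y_i)$ and C = 0.125, or
   per-action LDA fitted by variational EM with the converged per-document
   bound as the classification score.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `sigma_spatial`, `tau_temporal` | 2 px, 3 frames | detector scales |
| `omega` | 4/τ cycles/frame | temporal carrier; the classical cuboid-detector convention |
| `min_response_frac` | 0.05 (0.01 in the synthetic profile) | relative response floor for maxima |
| `nms_radius` | (4, 4, 3) | strict-local-maximum neighbourhood |
| `max_points` | 200/clip | interest-point budget |
| `n_ic` | 1200 (paper profiles), 64 (synthetic) | ICs per scale |
| `n_ic_clusters` | 480/440/32 | K-means clusters over Gabor descriptors |
| `n_struct_clusters` | 1000/700/64 | structural clusters per scale |
| Mc, Nc | SVM 2/400 (KTH), 1/500 (Weizmann), 1/50 (synthetic) | selection threshold and per-pair budget |
| grid | 3-1-1 or 1-1-1 | histogram pooling bands (vertical, horizontal, temporal) |
| `C` | 0.125 | SVM regularisation |
| `K_topics` | 50/30/8 | LDA topics per action |

The two `*-paper` profiles record the published benchmark settings for
reference; the `synthetic-small` profile scales every count to what a few
dozen 60×60×60 clips can support (64 ICs require ≥ 320 training patch
sequences; 64 structural clusters keep the NAS space, 64³ possible triples,
sparsely populated so selection has work to do). Its detector floor is 0.01
because the synthetic clips' response noise floor sits far below that of
real video.

## The synthetic generator

`generate_dataset()` emulates the structure of short single-action clip
collections: four registry actions (a bar sweeping back and forth, a pair of
bars oscillating in antiphase, a breathing annulus, a bouncing dot) chosen to
differ in both local orientation statistics and global motion, so both the
finest and coarsest scales carry class information. Subjects differ by
geometric jitter only — position offset, ±15% size, ±20% speed, drawn from
the subject seed — which makes leave-one-subject-out evaluation non-trivial
without changing appearance statistics. Pixel noise is i.i.d. Gaussian,
calibrated so sd(noise)/sd(clean) matches the requested SNR (20 dB ⇒ 0.1),
then clipped to [0, 1]; renders stay inside [0.1, 0.9] so clipping is
negligible. Every clip is a pure function of (action, subject seed, clip
seed).

What the generator does *not* emulate: articulated human figures, camera
motion, background clutter, appearance variation across subjects, and
compression artefacts. Passing the end-to-end benchmark therefore
demonstrates that the pipeline's stages compose correctly and that the NAS
representation separates geometrically distinct motions under noise, subject
variation and ±10% rescaling — not that the published human-action accuracy
transfers.

## Numerical choices

* **Disc mask.** The 13×13 circular mask is the centred digital disc with
  squared radius 40, i.e. 129 pixels — the count that fixes the flattened
  length 1419. Its row-major in-mask ordering is frozen and serialized with
  every codebook.
* **Borders.** Convolution uses reflection padding; patch cropping uses
  replicate padding, so interest points near borders remain usable in small
  clips.
* **Mean subtraction.** Each flattened patch sequence is mean-subtracted
  (standard ICA preprocessing); no contrast normalisation is applied.
* **Strict maxima.** Response plateaus are rejected; ties elsewhere break by
  frame, row, then column. `assign_nas` breaks centroid ties toward the
  lowest index; `select_nas` breaks score ties by smaller out-class
  frequency, then smaller NAS id; classifiers break label ties by class
  order.
* **K-means.** k-means++ initialisation, seeded restarts (10 for IC
  clusters, 5 for structural clusters), Lloyd iterations, minimum-SSE run
  kept, empty clusters repaired by splitting the largest. No standardization
  of the Gabor parameter space, and the angular coordinates are treated as
  plain Euclidean axes — the literal published procedure; this leaves a
  known seam at θ ≈ 0 ≡ π.
* **Histogram normalisation.** Before kernel evaluation each grid cell is
  L1-normalised and the concatenation rescaled to total mass 1. Equal total
  masses are what keep the 1−χ² kernel inside [0, 1] and positive
  semi-definite (on mass-1 vectors it equals the additive-χ² kernel
  $2\sum x_iy_i/(x_i+y_i)$); equal per-cell weights keep cells comparable.
* **LDA.** β is smoothed with a symmetric pseudo-count 0.01/C treated as a
  Dirichlet MAP prior *inside* the optimised objective, so the reported
  bound stays monotone (a plain post-hoc smoothing would break the EM
  guarantee). α is updated by Newton's method with the linear-time Hessian
  inversion and step-halving. Document length is ancillary and its Poisson
  parameter is not estimated. The classification score is the converged
  per-document variational bound.
* **Gabor fitting.** Fits minimise least squares over the 129 in-mask
  pixels with the amplitude solved in closed form; a negative amplitude is
  folded into a phase shift of π. Starts: an FFT-peak-derived guess plus 4
  seeded jittered restarts. In the pipeline only the highest-energy frame —
  the frame that defines the clustering summary — is fitted; per-frame
  fitting of all 11 frames is available via `fit_gabor(frames = "all")`.

## Design choices where the procedure was open

* **Reducing a spatiotemporal IC to one 6-parameter descriptor:** the
  highest-energy frame's fit. Per-frame fits exist and are returned, but a
  single descriptor per IC is what the clustering stage consumes.
* **"Occurring frequency"** for selection and statistics is the mean
  per-video relative frequency (counts divided by the video's total retained
  points), which makes videos of different lengths comparable.
* **The two selection desiderata** (rare in the other class, large
  frequency difference) are combined as one ranking score f_A − f_B with the
  tie-breaks above.
* **Scale robustness** re-extracts features from rescaled test clips with
  the fold's unchanged codebook; **noise robustness** perturbs the whole
  dataset and retrains, mirroring the respective published protocols.
* The LDA document score uses the variational bound as the tractable
  surrogate for the marginal likelihood.

## Problem sizes used by the shipped evaluations

The end-to-end benchmark runs 3 actions × 6 subjects × 3 clips of 60×60×60
voxels under the `synthetic-small` profile with leave-one-subject-out folds
and ±10% test-time rescaling; ICA subsamples at most 2500 patch sequences
per scale per fold. These sizes keep a full run on one CPU in the
single-digit minutes while leaving every count (patches per fold, NASs per
video) large enough for the statistics to be non-degenerate.

## Known limitations

* Angular parameters enter IC clustering as plain coordinates (seam at the
  orientation wrap); a circular-aware distance would remove the seam at the
  cost of departing from the published procedure.
* The Gabor summary discards temporal phase progression across the 11
  frames; ICs encoding pure temporal evolution with a static envelope are
  described only by their dominant frame.
* Video I/O covers frame directories (PNG, PGM); container formats would
  need an external frame extractor.
* With very few interest points per clip (sparse stimuli), NAS histograms
  are short; the SVM handles this gracefully, but LDA documents can become
  empty after selection, in which case the protocol falls back to the first
  class by the documented tie-break.
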