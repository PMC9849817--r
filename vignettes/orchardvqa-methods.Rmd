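---
title: "Methods: multimodal VQA for fruit-tree disease decision-making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal VQA for fruit-tree disease decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Visual question answering (VQA) for orchard disease management couples an
image $v$ with a free-text question $q$ and predicts an answer from a closed
answer set $A$:

$$\hat a = \arg\max_{a \in A} P(a \mid q, v, \Theta).$$

The architecture has four learnable stages.

**Input projections.** The image enters as a grid of $P$ position features of
$K$ channels (the backbone contract; $14 \times 14 \times 2048$ for the
reference ResNet-152 layout at a $448 \times 448$ input) and the question as
$T \le 26$ token features of dimension $J$. Learned linear maps project both
into a shared hidden width $h$.

**Stacked modular co-attention.** One MCA layer applies, in order: question
self-attention $SA(Y)$, image self-attention $SA(X)$, and question-guided
image attention $CA(X, Y)$ — queries from the image, keys and values from the
question, image on the residual path. Layers are stacked $L$ deep as an
encoder–decoder-style cascade. Each sublayer is pre-norm: $x + \mathrm{Sub}
(\mathrm{LN}(x))$, with ReLU feed-forward expansion and dropout on sublayer
outputs during training.

**Attended reduction.** A learned single-glimpse scoring (linear score,
softmax over unmasked positions, weighted sum) pools each final sequence to
$\tilde x$ (image) and $\tilde y$ (question). At zero-initialized scoring
weights this is the arithmetic mean, which is the neutral starting point.

**Tucker-decomposed bilinear fusion.** The full bilinear interaction tensor
$T \in \mathbb{R}^{d_q \times d_v \times |A|}$ is decomposed into factor
matrices $W_q, W_v, W_o$ and a core $T_c \in \mathbb{R}^{t_q \times t_v
\times t_o}$; each output slice of $T_c$ is further constrained to rank $R$
(a sum of $R$ outer products), giving $t_o R\,(t_q + t_v)$ core parameters.
The default variant squares the projected image vector element-wise before
the core contraction,

$$f = ((T_c \times_1 (\tilde y^\top W_q)) \times_2 (\tilde x^\top W_v)^2)
      \times_3 W_o + b_f,$$

which makes the score an even, quadratic function of the projected image
vector and re-weights the fusion toward image evidence. Plain Tucker
(equivalently the MUTAN-style path), MLB (Hadamard product of projections),
concatenation, and an additive-projection head
$z = \mathrm{LN}(W_x^\top \tilde x + W_y^\top \tilde y)$ are available as
alternatives. Training minimizes categorical cross-entropy with AdamW.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| heads | 8 | – | reference attention width |
| hidden $h$ | 512 | channels | reference hidden size |
| $L$ | 4 | layers | accuracy saturates at depth 4 |
| dropout | 0.5 | rate | regularization on linear/bilinear layers |
| LN epsilon | $10^{-12}$ | – | stated normalization constant |
| $t_q = t_v = t_o$ | 512 | channels | aligned with $h$ |
| $R$ | 15 | rank | low-rank core constraint |
| $G$ (glimpses) | 1 | – | independent image projections, concatenated |
| $d_z$ | 2048 | channels | bilinear-pooling head width |
| learning rate | $10^{-4}$ | – | reference AdamW rate |
| $\beta_1, \beta_2$ | 0.9, 0.999 | – | AdamW moments |
| batch size | 64 | records | reference mini-batch |
| max length | 26 | tokens | corpus maximum question length |

Two published settings conflict internally (a learning rate of 0.01 and
batch sizes of 100/128 appear in the same source's tables); the package
adopts the prose values (1e-4, 64) as defaults and leaves both overridable.
Desk-scale tests shrink $h$, $t_\ast$ and $L$; the reference values remain
one constructor call away.

`train_config()` also exposes `lr_decay`, a per-epoch multiplicative decay
(default 1 = constant). It exists because small-corpus memorization runs
oscillate near the optimum under a constant Adam rate; decay is the standard
remedy and does not alter the reference configuration.

## Synthetic data: what it emulates and what it does not

`generate_synthetic_corpus()` emulates the published corpus design at desk
scale: every image carries exactly two questions; every train/validation
question carries exactly three answer annotations; test questions carry
none; each question carries four multiple-choice candidates containing the
ground truth; splits pin validation and test at absolute counts with train
taking the remainder (the published 8,450 images divide 6,750/850/850, which
pure 8:1:1 rounding cannot reproduce).

Scenes are leaf-coloured squares (default 96 px — small enough for fast
tests, large enough that 4×4-patch features resolve lesion layout) with
$k$ elliptical lesions, $k$ drawn from `lesion_count_range` (default 0–5 so
"no disease" occurs), in one of four named colours. Questions are templated
per type: yes/no (disease present), number ($k$), what/where (lesion colour
or quadrant of the largest lesion), other (crop label). Annotations are
(truth, truth, deterministic in-type distractor), so the majority label —
the collapsed training target, ties broken by the first annotator — always
equals the ground truth, and the full answer is re-derivable from the stored
scene parameters.

The generator does **not** emulate: real leaf shape and venation, lighting
and perspective variation, label noise or annotator disagreement beyond the
single scripted dissent, open-vocabulary answers, or class imbalance between
disease kinds. A green test therefore establishes that the pipeline's
mechanics (encoding, attention, fusion, optimization, bookkeeping) are
correct and that the model class can fit data of this structure — not that
any accuracy transfers to field imagery.

## Numerical and design choices

- **Thresholding.** "Threshold set to 5 with Otsu" is read as
  $\max(\text{Otsu level}, 5)$: the Otsu scan stays the operative mechanism
  and 5 acts as a floor for near-black backgrounds; a constant image (no
  variance to maximize) returns the floor. Otsu runs on Rec. 601 luminance.
- **Morphology.** Opening (40×40 rectangle) runs on the thresholded mask at
  original resolution *before* the bounding box; out-of-frame pixels count
  as background, so border components erode like interior ones. The even
  structuring element anchors at the up-left-biased centre, and the dilation
  uses the reflected anchor so opening equals the union of contained SE
  translates. An empty post-opening mask falls back to the full frame.
- **Interpolation.** Bilinear with half-pixel centres (resizing to the same
  size is exactly the identity); rotation expands the canvas, inverse-maps,
  and centre-crops back; the aspect operator rescales width only.
- **Noise augmentation.** Variance 0.01 applies to unit-scaled intensities
  (the standard convention), clipped after addition.
- **Tokenization.** Punctuation becomes a space (never deleted inline, to
  avoid fusing words); word-piece training merges the most frequent adjacent
  pair (lexicographic tie-break) until the size cap (default 4000) or no
  pairs remain; unknown words map whole to `[UNK]`; sequences pad/truncate
  to exactly 26.
- **OOV projection.** Weighted least squares with uniform default weights
  (the source says "weighted" without defining them); underdetermined
  systems take the minimum-norm pseudoinverse solution, which reproduces the
  training pairs exactly.
- **Attention conventions.** A query whose keys are all masked yields a zero
  attention output (before the output projection's bias). Masked positions
  are never read by encoders or attended reductions; reducing an all-masked
  sequence is an error.
- **Guided-attention direction.** The layer name and the architecture
  diagrams imply image queries guided by the question, while one prose
  sentence says the opposite; the package implements question-guided image
  attention and exposes `swap_roles` to reverse it.
- **Candidates.** Four multiple-choice candidates are stored verbatim;
  training is open-ended classification over the answer vocabulary by
  default, and `predict_vqa(mode = "mc")` restricts the arg-max to the
  record's candidates (unscorable candidates are dropped). Ties resolve to
  the lowest index.
- **Fusion head.** The Tucker score (with bias $b_f$ kept in all variants)
  is the trained head; the additive-projection head is implemented exactly
  as printed and kept as a separate component, since the source presents
  both without specifying their composition. $G$-glimpse fusion is realized
  as $G$ independent image projections concatenated before the contraction —
  the only reading consistent with the stated dimensions.
- **Squared projection.** The raw element-wise square is kept (no signed
  square root), as the square itself is credited with reducing linguistic
  bias.

## The capacity check

The engine's acceptance-level check trains a tiny model (hidden 32, $L = 1$,
4 heads, core 32, $R = 4$) on a 20-image generated corpus (40 questions) to
strict accuracy 1.0 within 200 epochs, accepting success on any of three
seeds. It runs without regularization (dropout 0, weight decay 0) because it
measures memorization capacity, and with learning rate $10^{-2}$ decaying by
0.98/epoch rather than the reference $10^{-4}$: at desk scale 200 epochs are
only ~600 optimizer steps, and the reference rate belongs to corpus-scale
training. These values were fixed from standard practice for tiny
transformers before freezing the test.

## Known limitations

- No pretrained weights are shipped; the ResNet-152 path validates the
  shape contract at random initialization, and skip-thought/Bert/recurrent
  question encoders are declared contracts that error unless a backend is
  registered. Published corpus-scale accuracies are consequently not
  reproducible here and are not claimed.
- Training is single-threaded, per-example backprop on BLAS matrices:
  correct (finite-difference-verified) but not fast; it is meant for
  desk-scale corpora, ablation logic, and testing, not GPU-scale fitting.
- Images are read and written as PPM; standard PNG/JPEG corpora must be
  converted on ingest (any image tool can emit PPM).
- Reported reference statistics: the ten-run indicator table reproduces its
  published means on aggregation, but the published standard deviations are
  not consistent with any standard estimator on those rows, so only means
  are asserted; the package computes sample SD ($n-1$).
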