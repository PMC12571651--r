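---
title: "Methods: adapter-based alignment of dual-view radiographs and reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adapter-based alignment of dual-view radiographs and reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radalign)
```

## The problem

Radiology archives pair images (frontal and lateral chest projections)
with free-text reports. Visual-language alignment maps both into one
embedding space so that an image retrieves its report (and vice versa),
supports zero-shot classification via class-describing prompts, and can
be adapted to new tasks cheaply. Full-scale systems fine-tune large
pretrained encoders; the parameter-efficient alternative implemented
here freezes the encoders and trains only small *adapters*.

`radalign` implements the complete method surface at desk scale — every
operation is the real algorithm, exercised end to end on synthetic data
so that the package is testable on one CPU with no downloads.

## Model components

### Reversible adapter

The input embedding $e \in \mathbb{R}^h$ is split into halves
$e_1, e_2$ (first/last $h/2$ coordinates — the split ordering is a free
choice; we fix first-half/last-half, the common coupling-layer
convention). With bottleneck nonlinearities
$F(x) = U_F\,\mathrm{ReLU}(D_F x)$ and $G(x) = U_G\,\mathrm{ReLU}(D_G x)$
(each $h/2 \to h/4 \to h/2$), the forward map is the additive coupling

$$o_1 = F(e_2) + e_1, \qquad o_2 = G(o_1) + e_2, \qquad o = [o_1, o_2],$$

inverted exactly by $e_2 = o_2 - G(o_1)$, $e_1 = o_1 - F(e_2)$. The
inverse is algebraic, not numerical: the round-trip error is
floating-point rounding only (measured worst case $\sim 10^{-15}$ at
$h = 768$). All four maps are affine with biases — zero-initialized so
initialization never breaks neutrality — and weights drawn from the He
scheme $\mathcal{N}(0, 2/\mathrm{fan\_in})$.

### Transformer-Adapt layer

Each encoder layer exposes its hidden state $h_l$ and feed-forward
residual $r_l$. The language adapter and the task adapter are
bottleneck maps $h \to d \to h$ (defaults $h = 768$, $d = 64$):

$$LA_l(h_l, r_l) = U_l\,\mathrm{ReLU}(D_l h_l) + r_l, \qquad
  TA_l = U'_l\,\mathrm{ReLU}(D'_l\,LA_l) + r_l,$$

followed by one layer normalization over the $h$ coordinates. Two
readings of the printed task-adapter expression are possible; we add
the residual *outside* the nonlinearity, which is the only reading
under which the residual path is preserved when the up-projection is
zero. The layer norm sits after the task adapter, once per layer, and
its gain/shift are trainable alongside the task adapter (the
alternative — frozen norms — is not distinguishable from any statement
in the source method; we default to trainable and partition them with
the task family). The reversible adapter is applied once, to the token
embeddings of each encoder, rather than per layer; bottleneck adapters
sit in every layer. Both choices are configurable in spirit but fixed
in this artifact.

### Losses

Global alignment is one minus the cosine of the pooled embeddings;
local alignment averages per-region cosine distances over $n$
index-paired regions:

$$L = L_{\mathrm{GLOBAL}} + \lambda_1 L_{\mathrm{LOCAL}}, \qquad
  L_{\mathrm{GLOBAL}} = 1 - \cos(v_{img}, v_{txt}), \qquad
  L_{\mathrm{LOCAL}} = \tfrac1n \sum_i \left(1 - \cos(v_{img,i},
  v_{txt,i})\right),$$

with $\lambda_1 = 0.8$ by default. Region construction is not specified
by the method: we pool each modality's token sequence into $n$
contiguous, near-equal groups by mean ($n$ defaults to the smaller of
49 and the available token counts) and pair regions by index. This is
deterministic and order-preserving; learned attention matching is a
non-goal. The positives-only loss has a degenerate optimum (collapse of
all embeddings to one direction), which is irrelevant for loss
*evaluation* but fatal for toy retrieval *training*; an explicitly
non-source symmetric in-batch contrastive objective
(`batch_contrastive_loss`) is therefore available opt-in
(`objective = "contrastive"`).

## Image and text pipelines

Images arrive as Hounsfield-valued arrays. The chest window (width
1500 HU, level −500 HU) maps $[-1250, 250]$ HU linearly to
$\{0,\dots,255\}$, clipping outside; rounding is half-away-from-zero
(the convention is unstated upstream; any fixed convention satisfies
the "[0, 255] range" contract). Bilinear resizing to $224 \times 224$
uses a corner-aligned sample grid, then $16 \times 16$ patchification
yields 196 patches in row-major order. Masking is *exact-count*:
exactly $\lfloor 0.75 \cdot 196 \rfloor = 147$ patches are masked
uniformly without replacement, retaining exactly 49 — a Bernoulli
per-patch scheme would only achieve 49 in expectation, contradicting
the stated per-view count. Masks are resampled every epoch with a seed
derived from (base seed, record id, view, epoch), following common
masked-modelling practice; the two views of a record always use
distinct seeds. Missing pixels are filled by iterated 4-neighbour
means.

Reports are split on case-insensitive `HEADER:` markers; only the
findings and diagnosis sections are retained ("impression" and
"conclusion" are accepted diagnosis synonyms; the header map is
configurable), everything else — history, indications, requests — is
dropped. A report with neither section is flagged invalid rather than
erroring. Tokenization is a deterministic whitespace + punctuation
tokenizer with a stable hash vocabulary (no external vocabulary file
is needed; a wordpiece tokenizer can be plugged in behind the same
contract). Sequences are unified to exactly 128 tokens: right-padded,
or truncated at the last sentence boundary (`.` or `;` token) at or
before position 128, falling back to a hard cut when no boundary fits.

## Training runtime

The backbones are deliberately small frozen encoders: token embedding
(affine for patches, a lookup table for text) + position embeddings,
the reversible adapter, then per block a global-mean token-mixing step,
a ReLU FFN producing the residual $r_l$, the hidden state
$h_l = M + r_l$, and the Transformer-Adapt stack. We chose attention-free
mean mixing over multi-head attention deliberately: the package is pure
R with no autodiff, every backward pass is derived by hand and verified
against central finite differences (to $\sim 10^{-10}$ in the test
suite), and the mixer keeps that derivation short and auditable while
preserving everything the method's claims rest on — a frozen backbone,
adapters in every layer, the $h_l/r_l$ interface, and gradient flow
through the full depth. Nothing in the tested contracts depends on the
mixing operator.

Parameter partitioning follows the two training regimes: *pretrain*
trains all adapter families (reversible, language, task, layer norm)
and freezes backbones; *downstream* trains task adapters and their
layer norms only. Frozen arrays are bit-identical after any number of
steps — the optimizer never sees them. AdamW uses decoupled weight
decay $10^{-4}$ and per-group learning rates: $5\times10^{-5}$ for the
language family (reversible adapter included) and $10^{-4}$ for the
task family (layer norms included), batch 32. These defaults were tuned
upstream for BERT-scale encoders; the desk-scale test profile
($h = 32$, 2 blocks, 64 records, 150 steps) multiplies both by
`lr_scale = 100`, a standard Adam magnitude for a model this small.
That scale was fixed before the learning check was first run and is not
revisited.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` emulates the statistical structure the pipeline
assumes: dual views sharing one latent lesion, class-dependent lesion
geometry, and sectioned reports naming the class. Lesions are
Gaussian-profile rotated ellipses over an air-like background
($\approx -1000$ HU, noise sd 20 HU) with a soft-tissue thorax blob, so
the standard window renders real contrast; class identity sets the
lesion's clock-position, size, eccentricity and peak intensity, and the
lateral view places the lesion at a deterministic depth-compressed
reprojection of the frontal position (shared vertical coordinate) plus
independent noise. Reports are drawn from three templates per class
with Findings + Impression/Diagnosis sections. Defaults: 8 classes
(mirroring the 8-class × n-per-class retrieval-pool shape), 8 records
per class at desk scale, 224 × 224 pixels, all values in
$[-1024, 1000]$ HU.

What a green test does **not** establish: anatomical realism, reporting
language variability, scanner/windowing heterogeneity, label noise, or
any claim about performance on real archives. The synthetic world makes
class structure learnable by construction; passing the learning check
demonstrates that the adapter/loss/optimizer machinery is wired
correctly, not that the method reaches any published benchmark number.
Temporal (prior-study) views are named upstream but never specified;
"multiview" here means exactly {frontal, lateral} and the temporal
extension is unimplemented. No reconstruction loss exists for the
masked-modelling task (none is defined in the source loss), which we
note as a gap rather than inventing one.

## Numerical choices and degenerate inputs

* Layer norm uses population variance with $\varepsilon = 10^{-6}$;
  vectors of dimension < 2 are rejected.
* Cosine losses reject zero-norm vectors by name (modality, or region
  index); they are scale-invariant to well under $10^{-6}$.
* Ranking ties break by ascending candidate index; AUC uses midranks,
  which equals both exhaustive concordant-pair counting (always) and
  trapezoidal ROC integration (tie-free case).
* All seeds are 31-bit integers derived by a small-multiplier
  polynomial mix that is exact in double precision and stable across
  platforms; helper RNG never perturbs the caller's RNG state.
* Image IO is plain ASCII PGM (P2) — the text-native grayscale format —
  since no PNG/DICOM reader is available in the supported dependency
  set; DICOM ingestion is out of scope.

## Known limitations

* The encoders are toys; nothing here loads pretrained weights.
* The published trainable-parameter fraction and absolute parameter
  counts depend on an unstated backbone accounting and are not
  reproduced; the package reports its own census transparently
  (`partition_parameters()`).
* Zero-shot prompts are a single configurable template per class;
  prompt engineering is out of scope.
* UMLS term normalization, OCR watermark removal, and artifact-discard
  preprocessing require external resources and are stubs/non-goals.
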