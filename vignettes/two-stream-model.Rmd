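---
title: "A two-stream model of object search and invariant recognition in cluttered scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stream model of object search and invariant recognition in cluttered scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(visalscene)
```

## The problem and the model

In a cluttered natural scene, the ventral visual stream cannot identify
objects anywhere in the visual field: in clutter the receptive fields of
inferior temporal (IT) neurons shrink to a few degrees around the fovea. The
primate solution is sequential: a bottom-up saliency system in the dorsal
stream drives saccades to candidate objects, and the ventral stream then
identifies whatever sits within a few degrees of fixation. Because saliency
peaks rarely coincide with object centres, the ventral stream must supply
*translation* invariance over the residual fixation error on top of *view*
invariance across the object's possible poses.

`visalscene` implements both streams:

1. **Saliency (dorsal surrogate).** Intensity-contrast and orientation-energy
   feature maps at three dyadic pyramid scales (32, 16, 8 cells; colour and
   motion channels are deliberately absent — the recognition stream works on
   grayscale shape). Each map is turned into a fully connected Markov chain:
   the weight of the edge from node $j$ to node $i$ is
   $|\log(f_i/f_j)|\,e^{-d_{ij}^2/2\sigma^2}$ with $\sigma$ a fraction
   (default 0.15) of the map width. Outgoing weights are normalised and the
   equilibrium distribution is found by power iteration; mass accumulates at
   locations that differ from their spatial neighbourhood. A second,
   sharper Markov pass (edge weight proportional to the activation at the
   receiving node, $\sigma$-fraction 0.06, applied twice) concentrates each
   map's mass onto its peaks. Channel maps are averaged into a master map,
   thresholded, split into salient regions, and fixated at
   saliency-weighted centroids; a 384 px patch around each fixation goes to
   the recognition stream.

2. **Recognition (ventral model).** A four-layer hierarchy of competitive
   networks over a Gabor V1 front-end. Each neuron draws a fixed set of
   afferents from a Gaussian neighbourhood of its topologically
   corresponding position in the source layer, so receptive fields grow
   with depth until layer-4 neurons see the whole retina (checked at
   initialisation by graph reachability; the composed receptive field of a
   central layer-4 neuron must cover at least 95% of the retina).
   A forward pass per layer is: weighted sum over afferents, short-range
   lateral inhibition (centre-excitatory, surround-inhibitory filter with
   unit total mass, rectified at zero), then a sparseness-controlled
   sigmoid whose threshold sits at a per-layer percentile of the rescaled
   activations. Learning is the temporal-trace Hebbian rule
   $$\bar y_i(t) = (1-\eta)\,y_i(t) + \eta\,\bar y_i(t-1), \qquad
     \Delta w_{ij} = \alpha\,\bar y_i\,x_j,$$
   followed by L2 renormalisation of each neuron's weight vector. All
   transforms of one object are presented in a random permuted sequence and
   the trace is reset before the next object, so temporal contiguity binds
   exactly the transforms of one object onto the same neurons.

3. **Measurement and readout.** Stimulus-specific single-cell information
   $I(s) = \sum_r P(r|s)\log_2\!\big(P(r|s)/P(r)\big)$ with equi-spaced rate
   bins and uniform priors, reported for the cell's most effective stimulus
   (ceiling $\log_2 S = 2$ bits for 4 objects); cross-validated population
   information via nearest-class-mean cosine decoding and the mutual
   information of the resulting confusion matrix; and a one-shot Hebbian
   pattern associator (one output neuron per object) over the most
   selective layer-4 cells.

## Stimuli: what the generator emulates, and what it does not

The original study used rendered 3-D models of two people and two vehicles
on photographic backgrounds; neither is distributable, so the `stimuli`
module generates substitutes procedurally. Each object is a set of 3-D
ellipsoid parts (optionally with an oblique projected ellipse) rotated about
the vertical axis by the view angle, orthographically projected far-to-near,
and shaded with per-part albedo, a mild lighting gradient and deterministic
surface grain: a tall walker, a broad raised-arm figure, an open-top jeep
with a bright diagonal bar, and a bus with dark horizontal bands and a
periodic window row. The four classes were designed to be pairwise distinct
along several feature axes at once (dominant orientation energy, brightness
layout, aspect), because the real people and vehicles of the original study
are visually very distinct; with near-ambiguous part layouts a network this
small simply merges the ambiguous pair. Renders are 256×256, intensity
0–255, on a uniform 127 background; training canvases are 512×512 to keep
spatial filtering free of wrap-around.

Test scenes are 1024×1024: multi-scale filtered noise plus patchy texture
around mid-gray, two high-contrast distractor blobs (so the saliency map has
non-object peaks — typically six salient regions for four objects), and the
four objects pasted by their silhouette masks at jittered quadrant centres,
each in one of its four trained views, with exact ground-truth centres.

What the generator does **not** emulate: photorealistic shading, occlusion,
scale variation, background semantics, or within-class exemplar variability.
Passing tests therefore show that the *architecture* learns combined view
and translation invariance and survives synthetic clutter — not that it
would reach the same numbers on photographs.

## Parameters

| parameter | default (test / full) | meaning |
|---|---|---|
| layer grids | 32² / 128² | neurons per layer; full totals 65,536 |
| retina | 64² / 128² | V1 lattice; canvas block-averaged to it before filtering |
| Gabor bank | 4 orientations × {1/32, 1/16, 1/8, 1/4} c/px × 2 polarities | frequencies in cycles per lattice pixel, strictly below Nyquist |
| fan-in | 272 (L1), 100 (L2–4) | afferents per neuron; L1 channels sampled ∝ frequency² |
| conn. σ | 12 (L1, retina units); 5 (L2–4) | Gaussian afferent sampling radius |
| inhibition σ, δ | (1.38, 2.7, 4.0, 6.0), (1.5, 1.5, 1.6, 1.4) | surround width (grid-scaled) and gain |
| sigmoid percentile, slope | (.992, .98, .88, .91), (190, 40, 75, 26) | sparseness target and gain per layer |
| learning rates α | 0.05, 0.03, 0.005, 0.005 | per layer, applied uniformly at every presentation |
| trace η | (0, 0.8, 0.8, 0.8) | plain Hebb in layer 1; trace in layers 2–4 |
| epochs | 15 / 50 per layer | staged training, layer 1 upward |
| grid | 3×3 / 5×5 at 16 px | trained translations (views 270, 315, 0, 45°) |
| saliency | σ 0.15; norm σ 0.06 ×2; k = 6; threshold 0.2 | see below |
| readout | 10 bins; 25 cells/object; 5 folds | information measure and associator |

## Design decisions in detail

**Staged training.** Layers are trained successively (each for `epochs`
epochs with the layers below frozen and their outputs cached), the standard
protocol for this model family: each layer's feature combinations stabilise
before the next layer learns on them. Training all four layers
simultaneously (available via `staged = FALSE`, and the semantics of
`present(..., learn = TRUE)`) reproducibly failed to develop invariant
selective cells at this scale.

**Input normalisation.** Every layer's input vector is scaled to unit L2
norm before the forward product. The forward pass is scale-invariant anyway
(activations are rescaled to unit maximum before the percentile sigmoid),
but the Hebbian increment is not: without normalisation the raw V1 rates
(hundreds) made each layer-1 update an effective overwrite rather than a
slow average.

**Sigmoid rescaling.** The percentile threshold and slope operate on
activations rescaled by the layer maximum, so the dimensionless slope
defaults are meaningful for any input magnitude. An all-equal activation
pattern (e.g. a blank canvas) maps to uniform 0.5 in every layer — a
defined, logged, degenerate state rather than an error.

**Trace placement.** The trace is active in layers 2–4 and off in layer 1
(η = 0): layer 1 should learn position-specific feature analysers, while
invariance is bound progressively above. Both the placement and η are
configurable.

**V1 geometry.** The canvas is block-averaged down to the retina and
Gabor-filtered *at retina resolution*, keeping phase-resolved local
structure. The alternative — filtering at canvas resolution and pooling the
rectified responses — yields smooth orientation-energy maps from which the
hierarchy could not build object-discriminating conjunctions (layer 4 then
carried less object information than its input). Layer-1 afferents sample
frequency bands with probability proportional to frequency², the canonical
allocation, which also favours the translation-stable fine channels.

**Divergence guard.** Mean |Δw| per epoch normally rises briefly while
neurons first specialise, then decays; training aborts only when it grows
for five consecutive epochs *and* exceeds three times the pre-growth level.

**GBVS numerics.** Feature values are offset by ε = 10⁻⁶ × map-max before
logs; a uniform teleport weight of 10⁻⁶ keeps the chain ergodic; power
iteration uses the lazy chain (T + I)/2 — same equilibrium, provably
aperiodic, immune to the oscillations that near-bipartite dissimilarity
graphs otherwise cause; the proximity σ is floored at one map cell. The raw
equilibrium of a proximity-weighted chain on a bounded lattice is
centre-biased; both Markov passes therefore divide by the cached equilibrium
of the proximity-only chain (`boundary_correct`), which cancels the bias
exactly and makes a uniform map yield a uniform output. The equilibrium
solver itself is verified against a dense eigendecomposition oracle with the
correction disabled.

**Fixation extraction.** The master map is smooth (it is an average of
bilinearly upsampled coarse maps), so neighbouring objects' regions can
merge at any single threshold. Thresholded regions are therefore split at
saliency saddles by a watershed transform (minimum peak-to-saddle depth 0.1
of the map maximum), and centroids weight saliency cubed, pulling the
fixation toward the peak of a region rather than the middle of its skirt.
Both refinements are switchable back to plain connected components /
linear weighting.

**Cell selection for the readout.** For each object the 25 cells carrying
the most stimulus-specific information *about that object* are taken,
whether that information is conveyed by firing or by reliable silence; with
near-binary model cells, restricting selection to cells whose most effective
stimulus is the object starves some objects of cells entirely. The
pattern associator's output weight vectors are L2-normalised after the
Hebbian batch (the same synaptic scaling the network layers use), so
dot-product decoding is not biased toward objects with larger summed rates.

**Scaled-down profile sizes.** The `test` profile used throughout the test
suite trains 32×32 layers on 4 views × 9 locations for 15 epochs per layer
(about 75 s), and evaluates 16 scenes so that at least 48 object patches are
scored even when a few fixations land beyond the 64 px match radius. The
`full` profile mirrors the complete protocol (128×128 layers, 25 locations,
50 epochs); it is not exercised by the default test run.

## Known limitations

* Single fixation per object; no accumulation over saccades, no top-down
  attentional bias, no error-correction learning — all outside this model's
  scope by design.
* The information measures are plug-in estimates without bias correction;
  with ≥ 25 transforms per object the bias is small but nonzero (visible as
  a few hundredths of a bit on shuffled controls).
* Reflect-padding makes Gabor filtering only approximately
  translation-equivariant within a few kernel radii of the canvas border
  (relative deviations up to ~5% of the peak rate for the largest kernel).
* Performance numbers quoted anywhere in the documentation are produced by
  the test-profile runs of this package on its synthetic stimuli; they
  characterise the architecture, not any particular natural-image dataset.
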