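---
title: "Basin-mixture dihedral prediction: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basin-mixture dihedral prediction: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramamix)
```

## The model

`ramamix` predicts real-valued backbone dihedrals (φ, ψ) in two coupled
stages. First, training dihedral pairs are clustered into K Ramachandran
basins by k-means on the angle vector (cos φ, sin φ, cos ψ, sin ψ); the
trigonometric embedding makes Euclidean distance periodicity-aware, at the
cost that cluster centroids leave the torus and must be pairwise
renormalized back onto it. Second, a per-residue classifier predicts
marginal basin probabilities from sequence-derived features, and the
real-valued prediction mixes the normalized centers by those
probabilities, renormalizes, and converts back to angles.

The working assumptions are: (i) the dihedral distribution is a mixture of
a modest number of basins, each well approximated by a unimodal density on
the torus; (ii) a residue's basin is largely determined by its local
sequence context (a window of a few residues); and (iii) within-basin
spread dominates the reducible error once the basin is known, so the
probability-weighted within-basin variance is an informative error bar.
Assumption (iii) deliberately ignores between-basin variance: when the
classifier hedges between two distant basins the reported standard
deviation understates the error of the mixed point estimate. This is the
price of an error bar that is exact for confident predictions.

Per-basin densities use the bivariate von Mises cosine model,

$$f(\phi,\psi) \propto \exp\{\kappa_1\cos(\phi-\mu) + \kappa_2\cos(\psi-\nu)
  + \kappa_3\cos(\phi-\mu-\psi+\nu)\},$$

with locations μ, ν in degrees, marginal concentrations κ₁, κ₂ ≥ 0 and a
real interaction κ₃. These densities enter only the model-selection
likelihood, not the prediction path, so a moment estimator (circular means
plus inversion of A(κ) = I₁(κ)/I₀(κ) on mean resultant lengths) is
accurate enough; it is validated by parameter recovery on simulated
samples in the test suite. The interaction estimate inverts the same
relation on the resultant length of the deviation differences and takes
its sign from the circular correlation of deviations; this is known to be
biased upward when both marginals are tightly concentrated (the
differences are then concentrated regardless of any true interaction), so
κ₃ should be read as descriptive rather than inferential.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` (basins) | 20 | — | past the entropy-loss plateau on real-scale data; synthetic examples use the generating basin count instead |
| `n_init` (k-means restarts) | 10 | — | k-means++ seeding plus restarts makes label assignments reproducible in practice |
| `half_window` | 3 | residues | dihedrals depend on a short local context; a 7-residue window covers it |
| `n_blocks`, `hidden` | 5, 100 | — | a projection layer plus 4 residual blocks of width 100: enough capacity for the 66-feature task at CPU scale |
| `lambda` | 1e-4 | — | L2 weight penalty balancing fit and shrinkage; biases are unpenalized so an overwhelming penalty degrades gracefully to the background distribution |
| `epochs` | 20 | — | the objective plateaus well within 20 epochs at these scales |
| `epsilon` (K plateau rule) | 0.05 | nats | "within ε of the best entropy loss" operationalizes choosing the smallest K on the plateau |

Entropies and log-likelihoods are reported in nats; angles everywhere in
degrees, variances in degrees squared.

## Numerical choices

* **Normalizing integral.** The cosine-model integral has the Bessel
  series (2π)²{I₀I₀I₀ + 2Σ_p I_pI_pI_p}. For κ₃ ≥ 0 every term is
  positive and the series is summed in log space with exponentially
  scaled Bessel functions (stable to κ = 700), truncated at a relative
  contribution of 1e-14. For κ₃ < 0 the terms alternate and cancel
  catastrophically at large concentrations, so the ψ integral is taken
  analytically — ∫ 2π I₀(R(φ)) e^{κ₁cos φ} dφ with
  R(φ) = √(κ₂² + κ₃² + 2κ₂κ₃cos φ) — on a 4096-point periodic grid in
  log space, which is spectrally accurate for this smooth integrand.
  Both paths agree with brute-force torus quadrature in the tests.
* **Density scale.** The published form of the cosine model multiplies
  the exponential by the series expression, but that expression equals
  the integral of the unnormalized density; a density must divide by it.
  `dbvm()` does so and the test suite verifies unit mass by quadrature.
* **Concentration cap.** A(κ) → 1 as κ → ∞, so degenerate samples
  (resultant length within 1e-12 of 1) cap κ at 700, the largest value
  the scaled-Bessel arithmetic handles comfortably.
* **Angle convention.** Angles live in [−180, 180); +180 canonicalises
  to −180 so every angle has one representative. Undefined dihedrals
  (φ at the N-terminus, ψ at the C-terminus) are `NA`, never a sentinel
  value, and are excluded pairwise from every training and evaluation
  sum.
* **Variance space.** In-cluster variance is computed on angles, as the
  mean squared periodic deviation about the circular mean (degrees²),
  not on the trigonometric components. This makes the predicted standard
  deviation directly comparable to MAE in degrees, which is what the
  error-bound analysis plots.
* **Ties and degeneracies.** Nearest-center assignment breaks exact ties
  (after rounding squared distances at 1e-12) toward the lower cluster
  index. If a probability mixture cancels a (cos, sin) pair to norm
  below 1e-8 — possible when two basins sit at opposite φ — the
  prediction falls back to the highest-probability center and the record
  is flagged `degenerate`. k-means centers with a degenerate pair are
  re-seeded from a random member before normalization.
* **Cluster labeling.** Clusters are relabeled in order of decreasing
  size, so cluster 1 is always the dominant basin and serialized models
  are comparable across runs.
* **Monotone training.** The classifier trains by minibatch Adam, but an
  epoch that raises the full-data objective is rolled back and retried at
  half the learning rate (up to four times). The logged objective is
  therefore non-increasing by construction, a property the tests assert.
* **Label space.** Labels are assigned against the *normalized* centers,
  although k-means optimized the raw ones; the normalized centers are
  the quantities with an angular meaning, and they are what prediction
  mixes.

## What the generator emulates — and what it does not

`generate_protein_set()` produces proteins whose secondary-structure
strings follow a sticky 3-state Markov chain, whose dihedrals are drawn
from SS-conditioned bivariate von Mises basins at the canonical
Ramachandran locations (α, β, PPII, left-handed, broad coil), and whose
profile features are basin-specific templates plus Gaussian noise of
configurable scale. The coil basin is the broadest (κ ≈ 5–6, ~25°
spread) but still a distinct mode, so a clustering with K equal to the
basin count can recover every basin center — the generator's documented
contract, exercised in the tests.

The generator is a fixture, not a claim about real proteins. It does not
emulate: amino-acid-dependent dihedral preferences (glycine's mirror
symmetry, proline's φ restriction), correlations between neighbouring
residues' angles beyond the SS chain, evolutionary structure in the
profiles, missing or disordered regions, or the long tail of rare
conformations. Consequently, passing pipeline tests demonstrate that the
machinery — clustering, classification, mixing, confidence — composes
correctly and recovers a known generative truth; they do not establish
real-data accuracy, which depends on features and data the package
deliberately treats as inputs.

## Scale of the shipped experiments

The test suite and the acceptance script run the full pipeline on 100
synthetic proteins of length 50–150 (roughly 10⁴ residues), with K = 5
basins matching the generator, 15 training epochs and three seeds; moment
recovery uses 5·10⁴ draws and density checks use 512-point quadrature on
20 random parameter sets. These sizes were chosen as the smallest at
which the statistical claims (baseline improvement, confidence-error
correlation, recovery tolerances) are comfortably away from seed noise.

## Design decisions on open ground

Where the underlying procedure is not fully pinned down, the package
fixes conventions and documents them: amino-acid one-hot columns are
alphabetical by one-letter code; ensembles average member probability
matrices arithmetically and renormalize; profile values are consumed as
provided (no squashing) unless the caller transforms them; 8-state DSSP
labels reduce H,G,I→H and E,B→E with everything else coil; evaluation
PCC is pooled over residues rather than averaged per protein; the
error-bound fit is offered both on per-stratum means and on all residues,
with the per-stratum mode used by the acceptance script. The K-selection
plateau rule (smallest K within ε of the best entropy loss) is an
automation of what is otherwise a visual judgement; with the default
grid and real-scale data it lands on K = 20, which is also the package
default.

## Known limitations

Between-basin variance is excluded from the confidence score (see above).
The desk-scale classifier is a windowed residual dense network, not a
deep convolutional ResNet ensemble; the interface accepts any predictor
that returns simplex rows, and all downstream stages are agnostic to its
internals. The κ₃ moment estimator is descriptive. Finally, the mixing
step can interpolate across a saddle between two basins when the
classifier genuinely hedges; the `degenerate` flag and the top-R variant
(`top_r_mix()`) are the provided mitigations.
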