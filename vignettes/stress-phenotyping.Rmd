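---
title: "Detecting salt and drought stress from multi-modal leaf markers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting salt and drought stress from multi-modal leaf markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytostress)
```

## The problem and the modelling stance

Plants respond to drought and salinity with overlapping morphological
and physiological changes, so the interesting question is not "is this
plant stressed?" but "which stress, and how severe?". phytostress
frames this as *regression on severity levels*: each record carries a
drought severity $w \in \{0,1,2,3\}$ and a salinity severity
$s \in \{0,1,2,3\}$, and a model is scored by how well it recovers them
from 13 leaf-level features.

Three stress *scenarios* are evaluated:

* **drought** — predict $w$ on records with $s = 0$,
* **salinity** — predict $s$ on records with $w = 0$,
* **combined** — predict $(w, s)$ jointly on all records.

The single-stress scenarios use only the unconfounded rows (n = 60 of
240 under the default design) so that "drought prediction" is not
secretly exploiting salinity responses. An `subset = "all"` switch
keeps every row instead; the choice matters and neither is canonical,
which is why both exist. For the combined scenario one model is fitted
per output and the out-of-fold residuals of both outputs are pooled
before computing MSE and $R^2$ — "type and severity" names two
quantities, and pooling makes the score comparable across scenarios. A
single joint code (e.g. $4w + s$) was considered and rejected as the
default because it imposes an arbitrary metric between stress types,
but the two-output design keeps it reachable by evaluating each output
separately.

Severity is deliberately kept on the integer level scale rather than
physical units (mM NaCl, % field capacity): the two axes then share a
scale, and an MSE of, say, 0.25 reads directly as "half a level off on
average". Predictions are left continuous; nothing is rounded before
scoring.

## The support-vector regression core

No ε-SVR solver is available among the package's allowed dependencies,
so the solver is owned code. We use the dual formulation with the bias
absorbed into the kernel: minimize over $\beta \in [-C, C]^n$

$$\tfrac12 \beta^\top (K + 1)\beta - y^\top \beta
  + \varepsilon \lVert \beta \rVert_1 ,$$

where $K_{ij} = k(x_i, x_j)$ and the added constant 1 plays the role of
a (weakly regularized) intercept, a standard variant that removes the
equality constraint of the textbook dual. The problem is solved by
cyclic coordinate descent; each coordinate has a closed-form
soft-threshold-and-clip update, and the fitted values are maintained
incrementally (the inner loop is compiled). Predictions are
$f(x) = \sum_i \beta_i (k(x, x_i) + 1)$.

Numerical choices:

* **Stopping**: sweeps end when the largest coordinate change falls
  below `tol = 1e-6` or after `max_sweeps = 500`. On ill-conditioned
  problems (correlated features under the linear kernel) the descent
  approaches the optimum slowly; profiling showed metric values change
  only in the fourth decimal beyond 500 sweeps while cost doubles, so
  500 is the default budget. The iteration order is fixed, so results
  are deterministic regardless of convergence.
* **Standardization**: features are z-scored with training-fold
  statistics only, stored in the model and reapplied at prediction
  time. Constant columns get unit scale rather than an error.
* **Constants**: $C = 1$, $\varepsilon = 0.1$ throughout. Only the
  kernel parameter $\gamma$ is tuned — except for the linear kernel,
  which has no $\gamma$, where the optimizer tunes $C$ instead (some
  parameter must have been tuned for the tuned and untuned linear
  models to differ; this is the minimal consistent reading).
* **Kernels**: linear $x \cdot x'$, polynomial
  $(\gamma x\cdot x' + c_0)^d$ with $d = 3$, $c_0 = 0$, Gaussian
  $\exp(-\gamma\lVert x - x'\rVert^2)$, sigmoid
  $\tanh(\gamma x \cdot x' + c_0)$. The untuned default is
  $\gamma = 1/d_{\text{features}}$.
* **Degenerate inputs**: constant targets are a training error;
  an offset with no valid pixel pairs, an empty mask, or a constant
  observed vector in $R^2$ all raise typed errors rather than NaNs.

## Cross-validation protocol

Five folds by default, balanced to within one record, shuffled
deterministically under a seed. The aggregate MSE/$R^2$ are computed
in one pass over the pooled out-of-fold predictions, not as means of
per-fold values — pooled metrics stay well defined for small folds;
per-fold values are reported alongside. Plain row-wise folding is the
default for fidelity with the original protocol; because the design
has five repeated measures per pot, `group_by_pot = TRUE` is available
to keep whole pots in one fold (it typically lowers apparent skill,
which is exactly the leakage it prevents — off by default,
documented).

## Tuning by GA and PSO

Both optimizers are real-coded and work on log10-transformed boxes:
$\gamma \in [10^{-4}, 10^{2}]$, $C \in [10^{-3}, 10^{3}]$ (no bounds
are published; log-scale boxes are the field's standard for kernel
widths). Published configuration values are the defaults: GA runs 500
generations of 100 chromosomes with crossover fraction 0.5; PSO runs
100 iterations of 200 particles with inertia 1 and cognitive
acceleration 1. The remaining details are not published and default
to: tournament selection (size 2), BLX-0.5 blend crossover, Gaussian
mutation (rate 0.1, sd 10 % of the internal range), elitism 1; PSO
social acceleration 1 (set equal to the stated cognitive value) and
velocity clamped to 20 % of the range. There is no early stopping —
budgets run to completion, matching the fixed-budget description — and
the objective (pooled CV MSE on folds fixed once per tuning run) is
cached on parameters rounded to six significant digits. The default
parameter is seeded into the initial population, which guarantees
tuned MSE ≤ untuned MSE on the tuning folds. Candidates with
non-finite objectives are discarded via an infinite penalty.

A caveat worth stating: tuning on the same folds that produce the
reported score is optimistically biased. It mirrors the original
protocol as far as it is described; an inner/outer split would be the
hygienic alternative and can be built from the exposed primitives.

## Banzhaf feature importance

Features are players; the characteristic function $v(C)$ is the pooled
CV $R^2$ of the scenario model restricted to coalition $C$, with the
fold assignment fixed once and shared by *all* coalitions so that
differences in $v$ reflect features rather than resampling noise.
$v(\varnothing) = 0$ (the $R^2$ of no model; the mean-predictor
alternative is also 0 in expectation), and a coalition whose training
fails scores 0 with a warning. The raw index
$\beta_i = 2^{-(n-1)} \sum_{C \subseteq N \setminus \{i\}}
[v(C \cup \{i\}) - v(C)]$ may legitimately be negative — noise
features can hurt out-of-fold performance — so raw values are always
reported, and flooring at zero happens only when converting to
percentage shares. The exact engine enumerates all $2^n$ coalitions
(feasible for the per-family groups of 3, 6, 4, and even all 13); the
Monte Carlo estimator samples coalitions with each other feature
included with probability $\tfrac12$ (the distribution under which the
exact index is the mean), reports standard errors, and is seeded.

## The synthetic world

The generator emulates the factorial greenhouse experiment: 4 drought
levels × 4 salinity levels × 3 replicates = 48 pots, each sampled 5
times at 3-day intervals → 240 records. Every feature follows

$$x = \text{baseline} + a\,w + b\,s + c\,ws + d\,(t-1)
      + \mathcal N(0, \sigma^2),$$

independent Gaussian noise per feature (the simplest model supporting
parameter-recovery tests; no noise model is published). The default
directions encode the reported biology: image entropy falls under
stress while energy and homogeneity rise; RWC and CI fall; CA, AC,
PhC, PC rise; the miRNAs respond in stress-type-specific directions. A
small time drift is given to entropy, energy and CI (control leaves
darken over time); interactions default to zero.

The magnitudes are plausible placeholders chosen once — the real
per-treatment means and SDs are not published — and two structural
choices deserve explanation:

* **miR477b dominance.** The stock model must make miR477b the most
  informative miRNA and miR399g the least, because that ordering is
  the qualitative finding the end-to-end tests verify. Importance here
  is a *coalition marginal*, so magnitude alone is not enough: a
  strong feature collinear with another strong feature has small
  marginals. The defaults therefore give miR477b the largest
  signal-to-noise ratio on a response direction (drought-up,
  salinity-down) that the other miRNAs do not span, miR156a/miR166i
  weaker complementary directions, and miR399g near-zero slopes (a
  near-dummy player).
* **Family ordering.** Morphological features respond to the two
  stresses almost identically (total-stress responders), so the
  combined scenario cannot separate type from them; physiological
  features are partially type-specific; miRNAs strongly so. This
  reproduces the published miRNA > physiological > morphological
  ordering as a structural property, not as fitted numbers.

What the generator does **not** emulate: assay-specific measurement
error structure, heteroscedasticity, pot-level random effects,
temporal autocorrelation beyond a linear drift, or any electrochemical
sensor characteristics. A green end-to-end test therefore establishes
that the pipeline recovers the orderings *its own stated world
encodes* — it does not certify performance on real greenhouse data,
and the published headline values (combined $R^2$ of 0.61/0.82/0.99,
MSE 0.23, CA 33 %/RWC 6 %) are not reproducible targets without the
original dataset; on the synthetic defaults the miRNA family reaches a
combined $R^2$ near 0.9 (see the acceptance tests, which check the
orderings, not these magnitudes).

Leaf images are generated as Gaussian random fields whose correlation
length grows and whose amplitude shrinks with severity, so GLCM
entropy decreases and energy/homogeneity increase in expectation —
the direction of the reported image findings. An elliptical
`leaf_shape` variant on a dark background exercises segmentation.

## Texture stage choices

* Grayscale conversion uses the video-luminance weights
  0.299/0.587/0.114 (documented, fixed).
* Quantization: G = 8 equal-width bins spanning the declared gray
  range (no G is published; 8 keeps small-image GLCMs well
  populated). Because bin edges span the *declared* range, features
  are invariant to a constant gray offset applied consistently.
* GLCM: single displacement (0, 1) ("adjacent"), symmetrized by adding
  the transpose, both defaults overridable; optional averaging over
  the four standard directions. A pixel pair counts only if **both**
  pixels are in-mask.
* Entropy: natural log by default ("log" is unqualified in the source
  material; the base rescales entropy without changing orderings) —
  switchable to base 2 or 10.
* Segmentation: Canny (Gaussian blur σ = 1.4, hysteresis thresholds
  0.08/0.2 of the maximum gradient) followed by morphological closing;
  everything not reachable from the image border through edge-free
  space is foreground, and the largest connected component is the
  leaf. No parameters are published; these are conventional defaults.
  When no enclosed region exists the mask falls back to the full frame
  with a warning, so texture extraction still proceeds.

## Known limitations

* The published tables cannot be matched numerically even in
  principle: the target encoding, SVM flavor, $C$, $\varepsilon$, and
  scaling are unspecified, and the implied target variances across
  those tables are mutually inconsistent. The package treats them as
  qualitative orderings.
* The coordinate-descent SVR trades exactness for robustness; with the
  500-sweep budget on highly correlated linear-kernel problems the
  dual is solved to metric precision, not machine precision.
* Exact Banzhaf on all 13 features costs $2^{13}$ model fits ×
  5 folds; it works but is slow — the Monte Carlo estimator is the
  practical route there.
* The CLI is a thin convenience layer; programmatic use through the
  exported functions is the primary interface.
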