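---
title: "Conditional generative modelling of beating-heart mesh sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional generative modelling of beating-heart mesh sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cine cardiac imaging yields, for each subject, a sequence of triangulated
surface meshes of the cardiac ventricles across one heartbeat: `T` frames
of a fixed-topology surface with three labelled parts — the left
ventricular (LV) blood pool, the LV myocardium and the right ventricular
(RV) blood pool. Cardiac shape and motion vary strongly with demographics
(age, sex) and anthropometrics (weight, height), and with disease. A
*personalized normative model* asks: for a person with these clinical
factors, what does a typical healthy beating heart look like, and how far
does this particular heart deviate from that norm?

`cardiomesh` implements a conditional spatio-temporal variational
autoencoder over 3D+t mesh sequences, a seeded synthetic beating-heart
population to exercise it end to end, surface-distance and cardiac
phenotype metrics, and a normative deviation score (the *latent delta*)
with downstream classification and association harnesses.

# Model

## Architecture

All meshes share one template topology, so a frame is fully described by
its `V x 3` vertex coordinates (mm).

* **Condition encoder** — an MLP mapping the normalized conditions
  (z-scored age, weight, height; one-hot sex) to a 32-d condition latent
  `z_c`. Continuous conditions are z-scored with training-set statistics
  stored in the model state.
* **Mesh encoder** — three graph-convolution layers over the mesh edge
  graph (symmetric-normalized adjacency with self-loops,
  `D^{-1/2}(A+I)D^{-1/2}`), widths `3 -> 64 -> 64 -> 64`, mean-pooled over
  vertices (permutation-safe and memory-light), then one fully connected
  layer to the 64-d frame latent `z_t`.
* **Temporal transformer encoder** — the token sequence is
  `[mu_token; sigma_token; z_0 ... z_{T-1}]`, each token concatenated with
  `z_c` (token width `64 + 32 = 96`, divisible by the 4 attention heads).
  Two pre-norm blocks (LayerNorm before each sub-block, residual
  connections after both the self-attention and the MLP sub-block;
  feed-forward width 1024, dropout 0.1 during training). The two learnable
  distribution parameter tokens are read out at the output layer through
  linear heads to give the Gaussian parameters `(mu, log_sigma)` of the
  64-d sequence latent.
* **Reparameterization** — `z_a = mu + eps * exp(log_sigma)`,
  `eps ~ N(0, I)`. The second distribution token is interpreted as the
  *scale* (standard deviation) of the Gaussian, stored on the log scale;
  the KL term uses `sigma^2 = exp(2 log_sigma)` consistently. Evaluation
  (reconstruction, latent extraction) uses the posterior mean `eps = 0`;
  training samples `eps`.
* **Temporal transformer decoder** — sinusoidal temporal positional
  encodings of the frame indices (dimension 64, the dimension of `z_a`)
  are linearly projected to width 96 and serve as queries; the single
  key/value token is `[z_a; z_c]`. Two pre-norm decoder blocks
  (self-attention over the T queries, cross-attention to the key/value
  token, MLP), then a linear head back to 64-d per-frame latents. The
  pre-norm convention is applied to the key/value token as well: this
  keeps the decoder's input bounded whether `z_a` comes from the posterior
  (training, reconstruction) or from the standard-normal prior
  (generation), which stabilizes prior sampling.
* **Mesh decoder** — five fully connected layers from the frame latent
  concatenated with `z_c`: `96 -> 256 -> 512 -> 1024 -> 1024 -> 3V`. The
  output parametrizes per-vertex *displacements from the stored template
  shape*, in centimetres (converted to mm by a fixed factor of 10), and
  the template coordinates are added to give the `V x 3` frame.
  Template anchoring is the standard output parametrization for
  fixed-topology mesh autoencoders and matters doubly here: a pure
  Chamfer objective never enforces vertex correspondence, so an
  unanchored decoder can place vertices near the right surface while
  scrambling the identity of each vertex — the fixed faces then describe
  a crumpled surface with meaningless enclosed volumes. The centimetre
  units let the offsets reach anatomical scale within a desk-scale step
  budget at the fixed Adam learning rate. Faces come from the fixed
  template. At
  the cohort scale of the architecture (22,043 vertices, 50 frames) the
  parameter count is about 70.6 million, dominated by the final decoder
  layer.

The 64-d **latent vector** of a sequence — the feature used for
classification and for the latent delta — is the mean over the frame-token
positions of the transformer-encoder output, taken before
reparameterization. Our tokens are 96-d (frame latent plus condition); the
latent vector uses the first 64 columns, i.e. the residual stream aligned
with the frame-latent subspace. This avoids introducing an extra
projection that the training loss would never touch.

## Training objective

The loss is `L = L_R + L_KL + lambda_s * L_S` with

* `L_R`: mean over frames of the **Chamfer distance** between predicted
  and target vertex sets (the sum of the two directed mean
  nearest-neighbour distances);
* `L_KL = beta * KL(N(mu, diag sigma^2) || N(0, I))`, the beta-weighted
  KL divergence (`beta = 0.01`);
* `L_S`: mean over frames of the **Laplacian smoothness**, the mean over
  vertices of the norm of the mean neighbour-offset vector
  (`lambda_s = 1`).

Optimization is Adam at a fixed learning rate of `1e-4`, batch size one
mesh sequence, with no schedule, weight decay or gradient clipping by
default (clipping is available behind a flag for divergence recovery).
Parameters use Glorot fan-based initialization; the distribution tokens
start at `N(0, 0.02^2)`.

Because no deep-learning framework is involved, the package carries its
own small reverse-mode autodiff tape over matrix operations, with the
Chamfer/Laplacian kernels and the Adam update in compiled code. Gradient
correctness is pinned by finite-difference tests. Two numerical details
matter:

* the Chamfer gradient holds the nearest-neighbour assignment fixed (the
  standard subgradient); a finite difference across a weight that shifts
  *all* coordinates can therefore disagree slightly near assignment ties,
  which is why the end-to-end gradient test uses a smooth linear readout
  of the decoded coordinates;
* the directed distances guard against division by zero at coincident
  points (`d >= 1e-12`) in the backward pass only — loss values are exact.

# Synthetic population

Access-controlled cohort data cannot ship with the package, so the
`synthetic_population` module generates a population with *known* ground
truth. It emulates: a cyclic `T`-frame contraction; condition-dependent
chamber volumes, ejection fraction and mass; smooth inter-subject shape
variation; and disease perturbations.

* **Conditions** — sex ~ Bernoulli(0.5); age ~ U(45, 80) years; height and
  weight normal with sex-specific means (162±7 cm / 70±12 kg female,
  176±7 cm / 84±13 kg male).
* **Phenotype model** — `BSA = sqrt(weight * height / 3600)` (Mosteller);
  `LVEDV = 90 + 30*BSA + 20*sex - 0.3*(age-60)` ml;
  `LVEF = 60 - 2*(age-60)/10` %, clipped to [35, 75]; RV volumes are
  `1.05x` the LV analogues; wall thickness `8 + 1*sex` mm with mass =
  wall volume x 1.05 g/ml. Effect sizes were chosen once to give realistic
  adult ranges (LVEDV ~100–180 ml, LVEF ~50–70%). Optional noise adds
  `N(0, 8)` ml to LVEDV and `N(0, 2)` points to LVEF.
* **Geometry** — LV cavity: capped half-ellipsoid (long-axis/radius ratio
  3); myocardium: closed shell of constant thickness between the endo- and
  epicardial half-ellipsoids, joined by a basal annulus; RV cavity: a
  flattened half-ellipsoid bent into a crescent by a volume-preserving
  shear, placed laterally. Each part is scaled so its *measured*
  (discretized) volume matches the phenotype model exactly, which makes
  the noise-free generator/phenotype round-trip exact by construction.
* **Motion** — radial scaling about each part's long axis so that the LV
  volume follows `EDV - (EDV - ESV) * s(t)`, where the systolic phase
  `s(t)` rises as a half-cosine from 0 at frame 0 (end-diastole, the cine
  convention) to 1 at `round(0.35 * T)` (end-systole) and relaxes back.
  The myocardium follows the LV factor; the RV has its own.
* **Shape noise** — a per-subject superposition of six random
  low-frequency sinusoidal displacement fields (wavelength 30 mm), scaled
  to RMS `shape_sd = 2` mm. It is smooth at the mesh scale, preserves
  topology, and perturbs measured volumes by a few percent — the
  "measurement noise" of the study.
* **Disease** — `dilated`: LV volumes x `(1 + 0.4*severity)` at preserved
  EF; `hypertrophic`: wall volume x `(1 + 0.6*severity)`; `low_ef`: stroke
  volume of both ventricles x `(1 - 0.5*severity)` (so severity 1 halves
  the EF). Training uses the healthy split only, mirroring a normative
  model trained on asymptomatic hearts.

What the generator does *not* emulate: real anatomy beyond a closed
three-part topology (no valves, trabeculation, or long-axis shortening),
imaging/segmentation artefacts, or electrophysiology. Passing tests
therefore demonstrate that the method recovers structure *of this kind* —
condition-dependent size and motion amplitude under smooth shape noise —
not performance on clinical data.

# Evaluation and the latent delta

* **Reconstruction** — vertex-to-vertex Hausdorff distance and average
  symmetric surface distance per structure (LV, Myo, RV) and averaged,
  each over all frames and at the ED/ES frames. Vertex-to-vertex is
  well-defined here because all meshes share the template topology.
* **Phenotypes** — per-frame part volumes by the divergence theorem
  (signed tetrahedra); ED = argmax LV volume, ES = argmin (ties to the
  earliest frame); `EF = (EDV-ESV)/EDV x 100`; LVM = wall volume at ED x
  1.05 g/ml (the standard CMR density convention).
* **Generation fidelity** — for each phenotype, distributions of real vs
  generated values conditioned on age (decade bins) and sex are compared
  by KL divergence (histograms on shared Freedman–Diaconis bins over the
  pooled sample, additive smoothing `1e-8`, direction KL(real‖synth)) and
  by the exact one-dimensional Wasserstein distance (area between
  empirical CDFs), averaged over strata.
* **Latent delta** — `dz = || z_real - mean_i z_synth_i ||_2` with 100
  condition-matched synthetic reference sequences re-encoded through the
  mesh and temporal encoders. Both encodings use evaluation mode
  (`eps = 0`) so the score is deterministic given the reference seed.
* **Harnesses** — classification uses three pluggable kinds (boosted
  trees via xgboost, linear discriminant analysis, linear-kernel SVM) with
  AUCs averaged over five seeded random splits and a fixed AUC direction
  (no auto-flipping, so null features give AUC ≈ 0.5). The association
  scan fits a logistic regression of each binary outcome on the
  standardized latent delta and reports the Rao score test p-value with
  Bonferroni correction at family size = outcomes actually tested.

# Problem sizes and reproducibility

The package defaults to a desk scale chosen so a full study runs on one
CPU: 162 vertices per part (486 total), 20 frames, 50 training epochs on
60 healthy subjects. The cohort-scale configuration of the architecture
(22,043 vertices, 50 frames, 300 epochs) is reachable through
`model_config()`/`train_config()`/`population_spec()` but is GPU-scale
compute. `scripts/acceptance.R` runs a slightly smaller study (50
training subjects, 40 epochs, 20+20 subjects for the deviation score)
and writes every headline quantity it computes as JSON.

Everything is seeded: condition sampling, shape noise, parameter
initialization, data order, reparameterization draws, prior samples and
harness splits. Training twice with the same seed gives bitwise-identical
loss reports.

# Known limitations

* Vertex-to-vertex distances understate true surface distances when
  meshes are sampled differently; with shared topology this does not
  arise, but the metrics should not be compared against point-to-surface
  numbers from other pipelines.
* The latent delta reflects deviation *as seen by the encoder*; a
  perturbation the encoder is blind to (e.g. sub-resolution wall texture)
  will not raise it.
* The latent delta is a **weak per-subject disease score** at desk scale.
  Because the latent vector is a time average over the cycle, a motion
  abnormality confined to systole is diluted roughly three-fold relative
  to a static shape deviation of equal geometric size. In twin experiments
  (the same synthetic subject with and without a severity-0.8 low-EF
  perturbation) the disease moves the latent by about 0.26 units, while a
  healthy subject's own deviation from its condition-matched norm — driven
  by the population's phenotype and shape noise — is about 0.7 units. A
  Euclidean norm cannot detect a shift smaller than the deviation it is
  added to, so the delta's healthy-vs-low-EF AUC plateaus near chance even
  with perfect normative references, whereas the latent vectors themselves
  separate the same cohorts well when used as classifier features. This
  mirrors the score's intended use: population-scale association scanning
  rather than single-subject diagnosis.
* The synthetic population's linear phenotype model and ellipsoidal
  geometry are deliberately simple; effect-size recovery there does not
  calibrate clinical effect sizes.
* With a single key/value token, the decoder's cross-attention weights
  are degenerate (softmax over one key); content still flows through the
  value projection, and the structure keeps the stated architecture, but
  multi-token conditioning would be needed for the attention itself to be
  informative.
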