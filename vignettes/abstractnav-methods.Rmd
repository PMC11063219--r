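---
title: "Methods: simulating and analysing learning in abstract navigation spaces"
author: "abstractnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing learning in abstract navigation spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and its simulation

The task environment is a family of discrete abstract feature spaces: grids
of one, two or three dimensions with six values per dimension. A session
visits five spaces in the fixed order S1P, S2C, S2P, S1C, S3P; the first
space of each dimensionality forms Set 1 and the second forms Set 2, so a
Set 1 vs Set 2 contrast measures transfer of structural knowledge within a
dimensionality. In each space the subject completes 10 paths, each from a
random start to a random destination. At every step four candidate
locations around the current position are offered; choosing the destination
completes the path, and after any step in which the offered
distance-minimising option was not chosen the path terminates with
probability 0.20. Terminated paths keep their steps and enter all analyses.
Per step we record response accuracy (RA, 1 for a distance-minimising
choice) and response time (RT).

Three rules of the environment are under-determined by the task description
and are fixed here as package design choices:

* **Step metric.** Moves may change every coordinate by at most one
  (Moore moves, diagonals included), so the number of steps a perfect
  navigator needs is the Chebyshev distance. "Optimal option" therefore
  means a Chebyshev-distance minimiser among the offered options, with ties
  all flagged optimal.
* **Option pool.** Options are drawn without replacement from the in-bounds
  locations at Chebyshev distance 1 of the current location in 2-D/3-D
  spaces, and distance 1–2 in 1-D spaces (radius 1 would leave only two
  candidates there). Near corners fewer than four options are offered
  rather than padding with duplicates.
* **Progress guarantees.** The offered set always contains a pool member
  attaining the pool-wide minimum distance to the goal, and contains the
  goal itself whenever the goal is in the pool; otherwise paths could stall
  or never complete. An exhaustive check over all current/goal pairs
  verifies that a perfect agent always strictly reduces its distance.

### The synthetic agent

Real subjects supply no generative behavioural model, so the simulator
plants the two effects the analyses must recover — improvement across paths
and a Set 1 → Set 2 transfer advantage — with the simplest interpretable
curve. The latent learning level is logistic over the within-dimensionality
path index `t`:

`L(t) = plogis(k_learn * (t + transfer_offset * [Set 2] - t0))`

and the agent chooses an optimal option with probability
`q(L) = q_min + (q_max - q_min) * L`. RT is lognormal,
`exp(mu_rt - beta_rt * L + sigma_rt * eps)`, matching the positive skew of
reaction times. Defaults (`q_min = 0.35`, `q_max = 0.95`, `k_learn = 0.55`,
`t0 = 8`, `transfer_offset = 5`, `mu_rt = 0.6` log-seconds,
`beta_rt = 0.7`, `sigma_rt = 0.25`) were chosen once so that a default
cohort starts near chance, approaches ceiling within a 20-path
dimensionality group, and enters a Set 2 space roughly five paths ahead on
the curve — a visibly improving but noisy learner. `p_terminate = 0.20` is
the task's stated rule, not a free parameter. Inter-trial and fixation
intervals have no computational consequence and are not simulated.

For recovery tests, `simulate_session(level_fn = ...)` can override the
logistic schedule per path; the change-point cohorts used in testing plant
`L = 0` for paths 1–5 and `L = 1` for paths 6–10 of every space, with a
sharply separated agent (`q_min = 0`, `q_max = 1`, `beta_rt = 1.5`,
`sigma_rt = 0.1`), so the intended stage of every path is unambiguous.

## Learning level and staging

Each path is summarised by its N×2 matrix of (RA, RT) step rows. Paths 1–3
of each space are labelled early, 8–10 late, the rest mid. Within each
dimensionality group (1-D: S1P+S1C, 2-D: S2C+S2P, 3-D: S3P, in session
order) a feedforward classifier — dense layers of 64 and 32 ReLU units and
a 2-unit softmax head, categorical cross-entropy loss, full-batch Adam at
learning rate 0.001 for 100 epochs — is trained to discriminate early from
late paths, with two labelled paths withheld at random as the test set
(leaving 10 training paths in the 1-D and 2-D groups and 4 in the 3-D
group). Parameters are kept from the epoch with minimum test loss, and the
reported accuracy is the mean of the 100 per-epoch test accuracies, to be
compared against the 0.25 chance level (0.5 per label × 2 test paths).
P(early), the softmax probability of the early class for every path of the
group, is the path's estimated learning level, and a 2-means split of these
scalars — the cluster with higher mean P(early) becoming the exploration
stage — assigns each path a stage.

Numerical choices where the procedure is under-specified:

* **Fixed-length encoding.** Dense layers need a fixed input length. RT is
  min–max scaled to [0, 1] over all of a subject's steps, each path matrix
  is truncated to 20 rows or padded with sentinel (−1, −1) rows, and
  flattened row-major to 40 values. The sentinel is outside both feature
  ranges, so padding is identifiable.
* **Initialisation.** Weights start uniform in ±0.1 from the seeded
  stream; biases start at zero.
* **1-D 2-means.** An optimal 1-D 2-partition is a split of the sorted
  values, so Lloyd iterations are started from every sorted-split centre
  pair plus ten seeded random restarts; this attains the exact optimum
  (tested against an exhaustive-split oracle). An exact tie between
  cluster means raises an error rather than an arbitrary stage choice.
* **Degenerate inputs.** Constant P(early) vectors cannot be staged and
  raise an error; a zero-epoch configuration returns the initialised
  network with valid probabilities.

A known limitation, visible in the change-point recovery tests: with only
four training paths the 3-D group's classifier occasionally checkpoints at
epoch 1 (when the two withheld test paths happen to share one label and the
early training drifts toward the majority class), leaving a nearly flat
P(early) profile for that subject's 3-D group. This is a faithful property
of the estimation protocol, not of the simulator; recovery is therefore
evaluated pooled over paths, where it comfortably exceeds 90%. Similarly,
under default (transfer-planted) cohorts the early paths of a Set 2 space
are already well learned, so phase labels are intrinsically noisy there and
classifier accuracy sits well below the ceiling seen on separable cohorts —
as it must, since the transfer effect is real behaviour, not noise.

## Behavioral statistics

All three mixed models share one structure: per-path response (RA_path or
RT_path), one two-level fixed factor — learning phase (LMM1, early/late
rows only), set index (LMM2) or stage (LMM3) — and a random intercept for
every subject × dimensionality cell. The fixed factor is coded 1 for the
reference condition (early / Set 1 / exploration), so the reported effect
is reference minus comparison and planted learning yields negative RA
effects and positive RT effects. Fitting is REML via `lmerTest`, with
Satterthwaite degrees of freedom for the Wald t test (the default of the
standard mixed-model testing toolchain); if the Satterthwaite computation
fails, the normal approximation is used and recorded in `df_method`. No
random slopes are included — nothing in the design statement calls for
them. Auxiliary tests use base R: one-sample t of classifier accuracy
against 0.25 (with the directional one-sided p reported alongside), paired
t on exploration vs exploitation path counts, and a repeated-measures
ANOVA of accuracy over the three dimensionalities.

Power and calibration are established by simulating directly from the
random-intercept structure (25 subjects × 3 dimensionality cells, cell SD
0.05, residual SD 0.1, effect −0.15): 1,000 null and 1,000 effect
replicates give a type-I rate within [0.03, 0.07] and power above 95%.

## Synthetic neural patterns

The RSA consumes one volumetric parameter-estimate map per path. The
generator starts exactly there — no BOLD time series, HRF or GLM fitting is
simulated — on a 20×20×20 voxel grid (identity affine, nominal 2 mm
voxels) with an all-true brain mask by default. One or more cubic coding
regions (default: two 7³ cubes) carry a destination signal; remaining
in-mask voxels are i.i.d. Gaussian background (SD 1).

The destination signal is built so that pattern similarity depends on goal
separation *only*. Every location of a space is embedded with features from
the eigendecomposition of the radial-basis Gram matrix over all locations
(`bandwidth` 2 location units), so inner products of embeddings equal
`exp(-d²/2σ²)` of the goal distance exactly. Region loadings are
column-centred orthonormalised Gaussian draws scaled to unit per-voxel RMS:
centring makes every projected pattern exactly zero-mean over the region,
and orthonormality preserves inner products, so the noise-free neural RDM
of a region equals `1 − exp(-d²/2σ²)` — a deterministic monotone transform
of the theoretical goal-distance RDM, with identical ties. This is why the
noise-free limit reproduces a rank correlation of exactly 1, and why a
coding region must contain more voxels than embedding features. Stage
membership enters as additive noise: exploration maps get SD 0.8,
exploitation maps SD 0.2, planting the "destinations are represented more
accurately during exploitation" contrast in the simplest possible way.

What the generator does **not** emulate: spatial autocorrelation and
smoothness of real fMRI noise, anatomical region geometry, run-boundary
effects, signal magnitude differences across subjects. Passing recovery
tests therefore demonstrate that the analysis machinery detects the planted
effect under clean conditions, not that the effect is detectable in real
acquisitions.

## Searchlight RSA and group inference

The theoretical RDM of a set of paths is the Euclidean distance between
their destinations; the neural RDM is 1 − Pearson r between voxel
patterns; the two are compared by Spearman rank correlation (average ranks
for ties) over the strictly-lower triangles. A 3-voxel cube slides with
stride 1; a centre is valid when the full cube is in-volume and in-mask.
Euclidean distance between destinations of spaces with different
dimensionality is undefined, so RDMs are computed within space and the
per-space correlations are averaged with equal weight, per stage — a space
contributes only when the stage has at least 3 of its paths, and a space
whose destinations are all equidistant is skipped (rank correlation with a
constant is undefined). ρ-maps are Fisher-transformed (`atanh` after
clipping |ρ| at 1 − 1e−7, so degenerate ρ = ±1 stays finite), the
per-subject exploitation − exploration difference is tested voxelwise with
a paired t (voxels missing in any subject are excluded), and family-wise
error is controlled by sign-flip permutation of the subject difference
maps: each permutation recomputes the t map and its TFCE enhancement, the
null is the distribution of the volume-maximum enhanced statistic over
both signs, and the corrected p is `(1 + #{max ≥ observed}) / (n_perm + 1)`
(plain proportions when all `2^n` sign patterns are enumerated, which
happens automatically whenever `2^n ≤ n_perm`).

TFCE uses the field-standard defaults H = 2, E = 0.5, dh = 0.1 with
6-connectivity (26-connectivity available); the threshold sweep and
connected-component labelling are implemented in C++ since they run once
per permutation. Enhancement of a single isolated voxel of height h
converges to h³/3 as dh → 0, and disconnected clusters enhance
independently — both are used as oracles in the tests.

## Problem sizes and what the tests show

The test and acceptance suites size their simulations for a desk-scale run:
termination calibration uses ≥20,000 suboptimal steps; 2-means is checked
against the exhaustive oracle on 1,000 random vectors; staging recovery
uses 50 change-point subjects; mixed-model calibration uses 1,000 + 1,000
direct replicates; and the end-to-end RSA recovery uses 25 subjects on a
20³ volume with 500 permutations (the production default is 10,000). In the
end-to-end analysis, searchlights centred within one voxel of a coding
region genuinely see signal, so the false-positive rate is evaluated
outside a one-voxel box dilation of the regions; with that definition the
planted regions are flagged at FWE p < 0.05 across the large majority of
their voxels and the background false-positive rate stays far below 5%.

## Known limitations

* The behavioural learning curve, RT noise family and option-sampling rule
  are reconstructions; conclusions about the *method* transfer to real
  data, conclusions about effect sizes do not.
* The phase classifier inherits the instabilities of very small training
  sets (see above); its accuracy statistics should be read per cohort, not
  per subject.
* Neural noise is spatially white; TFCE's behaviour under smooth noise is
  exercised only through the permutation null, which is valid but less
  conservative than on real data.
* The 1-D option-pool radius of 2 makes 1-D "optimal" choices slightly
  different in character (a distance-2 jump and a distance-1 step can both
  be optimal); all analyses treat optimality uniformly through the flags.
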