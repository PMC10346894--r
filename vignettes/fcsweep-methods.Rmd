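---
title: "Methods: smoothing, connectivity, and decomposition in fcsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoothing, connectivity, and decomposition in fcsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what is simulated, how each stage is computed, which
conventions were adopted where the field has several, and what a passing
test does and does not establish.

## 1. The question the package addresses

Gaussian spatial smoothing is parameterized by the kernel's
full-width-half-maximum (FWHM). Small kernels under-suppress voxel noise;
large kernels blur signal across anatomical boundaries. `fcsweep`
quantifies, on a sweep of kernel sizes (default 0, 2, 4, 6, 8, 10 mm),
how the choice propagates into (a) FDR-thresholded functional
connectivity networks and their graph-theoretic summaries, and (b) the
shape (kurtosis, skewness) of group PCA/ICA spatial components — for
resting-state and task-based runs.

## 2. The synthetic cohort: a stated world

Real multi-subject scanner data of this design are not redistributable,
so the package ships a generative stand-in whose defaults encode the
emulated acquisition: a 24³ grid of 3 mm isotropic voxels, TR = 3 s, a
300 s resting run (100 volumes), an encoding run of 288 s (96 volumes)
with 24 stimuli of 6 s separated by 1 s gaps after a 30 s baseline,
20 subjects, and 32 ROIs grouped into 8 major-network blocks.

The generative model is deliberately the simplest one that makes
planted-edge recovery testable:

* **Node law.** A block correlation matrix Σ with unit diagonal,
  ρ_within = 0.6 inside blocks and ρ_between = 0.1 elsewhere (positive
  definiteness is checked; the default 32/8 configuration has minimum
  eigenvalue ≈ 0.4). Latent node series are Gaussian: X = Lᵀ Z with
  L the Cholesky factor of Σ and Z iid N(0, 1), rows standardized.
* **Subjects.** Per subject, the off-diagonal entries of Σ are perturbed
  on the Fisher-z scale by N(0, τ²) with τ = 0.1 — the same scale the
  analysis pipeline uses, so between-subject variance adds to the
  sampling variance of z̄ in the intended way. If the perturbed matrix
  loses positive definiteness it is repaired by eigenvalue clipping at
  10⁻⁶ and re-normalization to unit diagonal.
* **Voxels.** ROIs are discrete balls of radius 2 voxels (33 voxels
  each), placed by seeded rejection sampling with minimum center distance
  2·r + 1 so they are disjoint by construction. Every ROI voxel carries
  its node's latent series plus iid N(0, noise_sd²) noise
  (noise_sd = 1, i.e. noise at the same scale as the unit-SD signal);
  background voxels are pure noise. Task runs add `task_amp` times the
  haemodynamic regressor to every node's signal before embedding, which
  raises all pairwise correlations in the task state — a deliberately
  simple analog of task-coupled co-activation.
* **HRF.** The regressor convolves the stimulus boxcar with a canonical
  double-gamma response (gamma shapes 6 and 16, rate 1, undershoot ratio
  1/6) on a 0.1 s grid, samples it at the TR, and normalizes to unit
  peak. The single-trial response peaks 6–9 s after onset at TR = 3.
* **Seeds.** All randomness descends from one integer seed through a
  multiplicative derivation (`derive_seed`), with separate child seeds
  for the subject's correlation matrix, latent draw, and voxel noise —
  so cohorts can share latents while differing in noise, and every
  output is bit-reproducible.

Two encoding-run durations appear in the source design (the trial
sequence spans ~197 s while the encoding block is stated as 288 s); the
run length is therefore its own `task_design` field (`run_s = 288`),
with the trial block placed at its start. The emulated subject count is
20 (the design is also described with 23 in places); `n_subjects` is
configurable.

**What the generator does not emulate:** physiological noise (cardiac,
respiratory), head motion, scanner drift, spatial autocorrelation of the
noise field, anatomical geometry of real parcellations, and non-Gaussian
BOLD marginals. A green downstream test therefore establishes
correctness of the *computations* under a known ground truth — not that
real data would produce any particular value.

**The node-level fast path.** `simulate_group_timeseries()` produces the
per-subject node series the voxel renderer embeds, with node-level noise
SD = noise_sd/√33 (what ROI-mean extraction over a 33-voxel ball leaves
behind). The FDR-calibration and sensitivity simulations use this path —
rendering hundreds of full 4D cohorts would add cost but no information,
since ROI extraction of a rendered cohort provably recovers exactly
these series. The voxel path itself is exercised end-to-end at default
scale by the sweep criterion and the pipeline tests.

## 3. Smoothing

σ = FWHM / (2√(2 ln 2)); the discrete kernel lives on the voxel lattice
(σ_vox = σ_mm / voxel size, per axis, so anisotropic voxels are
supported) with taps at |k| ≤ ⌈3σ_vox⌉ ∝ exp(−k²/2σ_vox²), normalized
to sum 1. The truncation at 3σ captures > 99.7 % of the mass and is the
field convention; formulas that tie the kernel width to 1/FWHM are
dimensionally inconsistent (the width would shrink as FWHM grows) and
are not implemented.

Boundary policy: taps falling outside the volume are **dropped and the
remaining taps renormalized** — this is exactly the discrete weighted
average xᵢ = Σ wᵢ(k) xₖ / Σ wᵢ(k), makes smoothing exact on constants
everywhere, and (because the dropped region at any corner is a Cartesian
product of per-axis intervals) makes the separable implementation equal
the dense 3D convolution with joint renormalization to floating-point
precision — which is how the implementation is tested. `"zero"` and
`"reflect"` policies exist as options; `"renorm"` is the default and the
tested contract. FWHM = 0 is the no-smoothing reference and returns the
input bit-identically.

## 4. Connectivity and group inference

Node series are unweighted voxel means (the common toolbox default; the
aggregation is not part of the scientific claim), standardized, Pearson
correlated, and Fisher-transformed (z = arctanh r, with |r| clipped at
1 − 10⁻⁷ so noise-free synthetic inputs stay finite). The group
statistic per edge is the one-sample two-sided t-test of the subjects'
z-values against zero (df = n − 1) — the intercept-only GLM. Negative
edges count as connections (two-sided); `positive_only = TRUE` restricts
to positive ones.

FDR control is Benjamini–Hochberg over the full family of N(N−1)/2
edges jointly. The adjusted q-values come from `stats::p.adjust(method =
"BH")`; the step-up rejection rule is also implemented directly
(`fdr_threshold()`), and tests verify the two routes agree on random
inputs. Degenerate edges with zero across-subject variance get p = 1
(zero mean) or a 10⁻³⁰ floor (nonzero mean), with a message.

No nuisance regression or band-pass filtering is applied (the emulated
pipeline documents none); the task state is analyzed on the raw run, so
task-evoked co-activation is part of the task-state connectivity, as in
the emulated analysis.

## 5. Graph metrics: conventions on binary graphs

All five metrics operate on the binarized adjacency. Distances are
hop counts (the network is binarized before metrics, so correlation-
weighted path lengths do not apply).

* Global efficiency: (1/(N(N−1))) Σ_{i≠j} 1/d_ij with 1/∞ = 0.
* Local efficiency: mean over nodes of the global efficiency of the
  subgraph induced by the node's neighbours (nodes with < 2 neighbours
  contribute 0).
* Betweenness: Brandes accumulation; reported per node as
  Σ σ_ik(j)/σ_ik over unordered pairs, normalized by (N−1)(N−2)/2.
  The unnormalized sum is available (`normalized = FALSE`); the
  normalized convention is the one that puts dense 32-node graphs on the
  ~10⁻² scale typical of reported tables.
* Clustering: per node 2Tᵢ/(kᵢ(kᵢ−1)), kᵢ ≥ 2, else 0; network value is
  the unweighted node mean.
* Average path length: mean over *finite* distances only, with a
  `connected` flag reported alongside; an edgeless graph errors (and the
  sweep records zero metrics with `l_avg = NA` for that cell rather than
  aborting).

The implementation is validated exactly (10⁻¹² tolerance) against an
independent brute-force oracle that enumerates every simple path between
every node pair — exhaustively on all 33 858 labeled graphs with 2–6
nodes (33 866 graphs) and on seeded random 8-node graphs.

## 6. PCA, ICA, and component shape

The group matrix stacks subjects along time after per-voxel
standardization within subject; voxels constant in any subject are
dropped and recorded. PCA is exact: eigendecomposition of the smaller
Gram matrix, spatial maps = right singular vectors (orthonormal),
explained-variance ratios attached, sign fixed so each map's
largest-magnitude voxel is positive. ICA is FastICA with the log-cosh
contrast and symmetric decorrelation, whitened to n dimensions via PCA,
fixed-point iteration to tolerance 10⁻⁴ or 500 iterations
(non-convergence warns and flags the result), deterministic given the
seed. A per-component negentropy proxy J = (E[log cosh s] − E₀)² is
attached; if every component's J is ~0 the data are effectively
Gaussian and the result is flagged unidentifiable.

Shape statistics are computed on the **spatial maps** (the voxel
dimension): skewness m₃/m₂^{3/2} and kurtosis m₄/m₂², reported as
*excess* kurtosis (Gaussian → 0) by default with the raw value behind a
flag — the deviation-from-Gaussian reading is the one of interest, and
either convention is a constant shift. Cross-kernel comparison uses
two-sided Welch two-sample t-tests on the per-component values for every
kernel pair (robust to unequal variances; the emulated analysis names no
test), giving a symmetric p-value matrix with unit diagonal. n = 40
components is the default; component-number selection is out of scope.

## 7. The sweep and its acceptance analog

`run_sweep()` renders one cohort per state (rest: the config as given;
task: the 96-volume block-design variant), then for each FWHM smooths
every subject, rebuilds the networks, computes metrics, and collects
PCA/ICA shape statistics; smoothing always precedes connectivity and
decomposition. fwhm = 0 cells are bit-identical to a pipeline with no
smoothing stage.

The headline empirical claims of the emulated study (its metric tables
and component statistics) were computed on unreleased scanner data and
are not reproducible at desk scale. The package's acceptance suite
therefore checks the *qualitative* finding on the synthetic cohort:
global efficiency varies by ≤ 10 % relative range across the kernel
sweep in both states (the gated invariant), while mean edge strengths —
and, in the resting state, significant-edge counts — change with the
kernel. The other four metrics' relative ranges are reported rather than
gated: normalized betweenness in particular has a mean of order 10⁻²–0,
so its relative range is an ill-conditioned gauge (it is exactly 0/0
when a state saturates at the complete graph, which the task state does
under the default all-node task amplitude). On the default cohort the
mechanism is visible: wider kernels average away voxel noise, the
Fisher-z values rise, more of the 496 candidate edges pass the FDR
threshold, and the graph densifies slightly — but the metric summaries
barely move. The
ICA-kurtosis trend across kernels is reported alongside (not gated): on
this noise model the smoothed maps' tails need not grow the way real
data's do, and gating on it would test the generator, not the method.

## 8. Numerical choices and degenerate inputs

* Fisher clipping at 1 − 10⁻⁷ bounds |z| ≈ 8.4, far above any group
  mean of interest, while keeping noise-free inputs finite.
* The planted-Σ constructor and the per-subject perturbation both check
  positive definiteness; repair is by eigenvalue clipping at 10⁻⁶.
* `p.adjust`-based rejection uses q ≤ α, identical to the step-up rule.
* ROI placement failure (grid too small for the requested disjoint
  balls) errors with the violated constraint after a bounded number of
  rejection draws.
* NIfTI I/O stores float64 and reads both endiannesses, applying
  scl_slope/scl_inter; round trips are bit-exact. Only single-file
  NIfTI-1 is supported.
* All t-based p-values are computed directly from `pt`; tests cross-check
  against `stats::t.test` so the vectorized formulas cannot drift.

## 9. Known limitations

* The noise model is iid Gaussian per voxel; spatially correlated noise
  would change how edge counts respond to smoothing (the qualitative
  direction, not the machinery, depends on this).
* The adjacency is built from a one-sample t on Fisher-z values;
  covariate-adjusted group models are out of scope.
* Weighted-graph metrics, modularity, small-world indices, dynamic
  connectivity, and voxel-to-voxel connectivity matrices are out of
  scope by design.
* FastICA here is the textbook symmetric log-cosh variant; it is
  validated for source recovery on super-Gaussian mixtures, not tuned
  for speed on very large component counts.
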