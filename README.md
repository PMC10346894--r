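# fcsweep

Smoothing-sensitivity analysis for group-level fMRI functional
connectivity, in R.

Spatial smoothing with a Gaussian kernel is a near-universal fMRI
preprocessing step, but the kernel's full-width-half-maximum (FWHM) is a
free parameter with real consequences downstream: it changes which edges
of a functional connectivity network survive thresholding, and it changes
the shape of the spatial components that PCA and ICA extract. `fcsweep`
packages the full analysis chain needed to quantify those effects on a
sweep of kernel sizes (0, 2, 4, 6, 8, 10 mm by default), for resting-state
and task-based runs:

1. **Synthetic BOLD cohorts** — multi-subject 4D volumes (default
   24×24×24 voxels of 3 mm, TR = 3 s, 100 volumes, 20 subjects) with 32
   spherical ROIs grouped into 8 network blocks and a *planted*
   node-correlation matrix (ρ = 0.6 within blocks, 0.1 between), plus an
   optional block-design task run (24 stimuli of 6 s + 1 s gaps over
   288 s) convolved with a canonical double-gamma haemodynamic response.
   Because ground truth is known, every downstream stage is testable.
2. **Gaussian smoothing** — separable convolution with
   σ = FWHM / (2√(2 ln 2)), taps truncated at ⌈3σ⌉ voxels, and
   drop-and-renormalize boundary handling, so the smoothed voxel is the
   weighted average x̂ᵢ = Σₖ wᵢ(k) xₖ / Σₖ wᵢ(k) at every position
   including edges (constants are preserved exactly).
3. **Connectivity networks** — ROI-mean time series, Pearson correlation,
   Fisher z = arctanh(r), per-edge one-sample t-tests across subjects and
   Benjamini–Hochberg FDR thresholding (q < 0.05) over all N(N−1)/2
   edges, binarized into an adjacency matrix. A 32-node analysis has
   exactly 496 candidate edges.
4. **Graph metrics** — global efficiency E_glob = ⟨1/d_ij⟩, local
   efficiency (mean efficiency of each node's neighbour subgraph),
   normalized betweenness centrality, clustering coefficient, and average
   shortest path length (finite pairs), all on binary graphs, validated
   exactly against a brute-force path-enumeration oracle.
5. **PCA / ICA shape statistics** — group PCA (exact, via the Gram
   matrix) and FastICA (log-cosh contrast, symmetric decorrelation) with
   n = 40 components by default; per-component spatial-map skewness
   m₃/m₂^{3/2} and excess kurtosis m₄/m₂² − 3, and pairwise Welch-t
   p-value matrices across kernel sizes.
6. **The sweep** — `run_sweep()` orchestrates everything per (FWHM,
   state) and emits a metric table, per-kernel edge lists/counts, and
   component shape summaries.

Images are read and written as NIfTI-1 (`.nii` / `.nii.gz`) with a
built-in minimal reader/writer (float64 storage, lossless round trips) —
no external imaging dependency is needed.

## Worked example

```r
library(fcsweep)

res <- run_sweep(
  sweep_config(fwhm_list = c(0, 6, 10), states = "rest",
               n_components = 10, seed = 42),
  sim_config(n_subjects = 10, seed = 42))

metrics_table(res)
#>    kernel rest_e_glob rest_e_loc rest_bc_mean   rest_cc rest_l_avg
#> 1     0mm   0.7664651  0.7948319   0.01565860 0.5902370   1.469758
#> 2     6mm   0.7674731  0.7934694   0.01559140 0.5884074   1.467742
#> 3    10mm   0.8225806  0.8342193   0.01182796 0.6684762   1.354839
#> 4 Average   0.7855063  0.8075068   0.01435932 0.6157069   1.430780

edge_report(res)$counts
#>   state kernel n_edges
#> 1  rest    0mm     265
#> 2  rest    6mm     266
#> 3  rest   10mm     320
```

Reading: as the kernel widens, voxel noise is averaged away, node time
series get cleaner, more of the 496 candidate edges pass the FDR
threshold (265 → 320 here), and the graph becomes slightly denser — so
E_glob rises and the path length falls — yet all five metrics move by
only a few percent while the edge count moves visibly. That stability of
graph-theoretic summaries against kernel choice, in contrast to the
sensitivity of the edge sets themselves, is precisely the phenomenon the
package is built to study. With the default 40-component decomposition,
`res$results$rest$...$ica_stats` additionally tracks how the spatial-map
kurtosis/skewness distributions respond to the kernel.

## Command line

A thin CLI lives at `inst/cli/fcsweep` (installed under
`system.file("cli", "fcsweep", package = "fcsweep")`):

```sh
fcsweep simulate --config cfg.json --out cohort/ --seed 17
fcsweep smooth   --in cohort/sub-01.nii.gz --fwhm 6 --out sub-01_s6.nii.gz
fcsweep connect  --images cohort/ --atlas cohort/atlas.nii.gz --q 0.05 --out conn/
fcsweep metrics  --adjacency conn/adjacency.tsv --out metrics.tsv
fcsweep decompose --images cohort/ --method ica --n 40 --seed 7 --out dec/
fcsweep sweep    --out sweep/ --seed 3
```
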