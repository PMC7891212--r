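---
title: "Mapping connector hubs in frequency-binned multilayer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping connector hubs in frequency-binned multilayer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Different neuronal populations communicate at different rhythms, and some
regions appear to act as *connector hubs* that couple activity across
frequencies. multihub implements a pipeline that maps such hubs from
source-space MEG-like time series: functional coupling is estimated within
and between narrow frequency bins, constrained to anatomically plausible
connections, assembled into one *full multilayer* network (layers = bins,
with arbitrary node-to-node interlayer edges rather than only
replica-to-replica coupling), and interrogated with two centrality notions —
multilayer versatility for hub detection and delta centrality on
interconnectedness (DCI) for reranking hubs by their importance for
cross-frequency communication.

## Pipeline and model

For a node pair $(i, j)$ and bins $(a, b)$, coupling is
amplitude–amplitude coupling (AAC): the Pearson correlation of the Hilbert
amplitude envelopes of the band-filtered signals,
$r_{ij}^{ab} = \mathrm{cor}(\mathrm{env}_a(x_i), \mathrm{env}_b(x_j))$,
computed within bins ($a=b$) and between bins from low to high only
($a<b$). The stages are:

1. **Broadband conditioning** (optional): zero-phase band-pass 0.1–100 Hz
   plus a sharp DFT notch at the line frequency.
2. **Symmetric orthogonalization**: node time courses are replaced by the
   closest (least-squares) set of mutually orthogonal signals, treating all
   nodes symmetrically, to suppress zero-lag signal leakage. Trials are
   concatenated first so the rank requirement is met.
3. **Binning and envelopes**: equal 5 Hz bins (0.5–50.5 Hz by default);
   envelopes are computed on the full epoch and only then cropped to the
   analysis window (0.8–1.3 s), keeping filter and Hilbert edge artifacts
   outside the retained samples.
4. **Surrogate normalization**: 100 IAAFT surrogates per node (and per
   trial) destroy all genuine coupling while preserving each signal's
   amplitude distribution exactly and its power spectrum approximately; the
   empirical coupling is z-scored against the per-connection surrogate mean
   and standard deviation.
5. **Thresholding**: each z-matrix is thresholded with orthogonal minimum
   spanning trees (OMST): successive edge-disjoint maximum-weight spanning
   trees are unioned while the global cost-efficiency objective
   $J = \mathrm{GE}_{norm} - \mathrm{Cost}$ improves, then multiplied
   entry-wise by the binary structural connectivity matrix.
6. **Supra-adjacency**: the $B$ within-bin matrices form the block diagonal
   and the $B(B-1)/2$ between-bin matrices the off-diagonal blocks of an
   $(N \cdot B) \times (N \cdot B)$ symmetric supra matrix.
7. **Hubs and DCI**: multilayer versatility (PageRank on the supra graph,
   aggregated over a node's layer replicas) is z-scored across nodes; nodes
   with $z > 2$ are hubs. For each hub, DCI is the percent drop in
   interconnectedness (the count of interlayer edges) when the node's rows
   and columns are zeroed in every layer:
   $\mathrm{DCI}(v) = 100\,(I_{full} - I_{-v})/I_{full}$.
8. **Group inference**: per-node scaled DCI values across subjects enter a
   one-sample, one-tailed sign-flip permutation test of mean $> 0$
   (exhaustive enumeration up to $2^{12}$ sign patterns, 5000 random flips
   otherwise).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| bins | 0.5–50.5 Hz, width 5 | Hz | equal-width cross-frequency grid |
| analysis window | 0.8–1.3 | s after stimulus | task-evoked coupling window |
| surrogate window | 0–epoch end | s | nulls built on the task period |
| `n_surrogates` | 100 | count | stable per-connection null mean/sd |
| `hub_threshold` | 2 | z units | captures the fat tail of the versatility distribution |
| `n_permutations` | 5000 | count | group-test resolution ~2e-4 |
| `damping` | 0.85 | – | standard PageRank teleportation |
| `count_replica_pairs` | TRUE | – | replica self-pairs count as interlayer edges |
| `pool` | concatenate | – | trials concatenated before correlation |

The hub threshold is meaningful when the node count is large enough for a
fat-tailed centrality distribution; with $n$ nodes the population z-score
cannot exceed $(n-1)/\sqrt{n}$, so very small demo networks rarely produce
$z > 2$ hubs — a property of z-thresholding, not of the implementation.

## What the synthetic generator emulates — and what it does not

`generate_coupled_timeseries()` produces $1/f^{\alpha}$-plus-white noise
per node with band-limited oscillations whose amplitude envelopes share a
slow common modulator between planted node/bin pairs; the mixing weight is
the coupling strength, so AAC — and nothing else — is planted. A planted
`hub_node` is coupled across every low/high bin pair (of the first four
bins) plus two within-bin pairs — more than the three bin pairs that
minimally define a cross-frequency connector — making it simultaneously a
strong centrality hub and an interfrequency connector. The modulator is
low-pass noise below 2 Hz, near the fastest envelope fluctuation a 5 Hz-wide
band can carry; because it is slow, envelope samples inside a short analysis
window are strongly autocorrelated and coupling estimates gain precision
mainly from additional trials.

`generate_structural_matrix()` is a stochastic block model (within-module
edges 4x more probable than between) rejected until connected.
`ensure_structural_support()` sets the structural connection of every
planted pair to 1: coupled sources communicate along anatomical
connections, and a synthetic cohort should not mask out its own planted
coupling. `generate_multilayer_fixture()` skips the signal stages entirely
and plants a connector at the network level, guaranteeing the hub at least
twice the interlayer edge count of any other node (thinning background
edges if necessary), which makes it the exact DCI optimum by construction.

None of this emulates real head geometry, beamformer leakage structure,
heteroscedastic sensor noise, or physiological artifacts. Passing tests
therefore demonstrate that the pipeline recovers the statistical structure
it is designed to detect, not that it is robust to every property of real
MEG recordings.

## Numerical choices

- **Filters** are zero-phase FFT filters with 1 Hz raised-cosine
  transitions. Forward–backward IIR filtering is the more common
  implementation, but 5 Hz-wide passbands near 0.5 Hz on short epochs make
  high-order recursive filters numerically fragile; spectral multiplication
  with a real gain is exactly zero-phase and meets all attenuation
  requirements by construction.
- **Orthogonalization** alternates a polar decomposition with a diagonal
  rescaling (closest orthogonal matrix, symmetric in the nodes); it stops at
  a relative objective change below 1e-12. Rank-deficient input is an error,
  not a warning: leakage correction is undefined there.
- **IAAFT** stops when the relative change in spectral amplitude error
  falls below 1e-6 or at 100 iterations; the last step is always the rank
  remap, so the amplitude multiset is preserved exactly.
- **OMST** breaks weight ties lexicographically by node index, making the
  retained network deterministic; negative z-scores are clipped to zero
  before thresholding (a connection weaker than its null should never form
  an edge); the diagonal of symmetrized between-bin blocks
  (cross-frequency self-coupling) is dropped at this stage because
  spanning-tree machinery is defined on simple graphs — the structural
  mask, whose diagonal is zero, would remove it anyway. Disconnected input
  falls back to a flagged maximum spanning forest.
- **Degenerate nulls** (`sd_null = 0`) produce z = 0, not infinity, so a
  degenerate connection can never become an edge, and the count is logged.
- **sd conventions**: the surrogate null uses the sample (n−1) standard
  deviation; node z-scoring uses the population convention by default, both
  configurable and documented.
- **DCI scaling** divides by the standard deviation over candidates
  *without* centering: most DCI values are exactly zero (removing a node
  with no interlayer edges changes nothing) and that zero is meaningful.
  Mean subtraction would shift it.
- **Sign-flip test**: exhaustive enumeration whenever $2^{n} \le 4096$
  gives exact p-values (including the identity pattern, so $p > 0$ always);
  the random branch uses the (1 + count)/(1 + draws) estimator.

## Design choices where the design was open

- The group candidate rule is "hub in at least one subject" (configurable
  `min_hub_subjects`), with non-hub subjects contributing a DCI of 0 —
  consistent with treating absence from the hub set as absence of
  connector behaviour, not as missing data.
- Surrogates are generated from the already-orthogonalized signals;
  re-orthogonalizing each surrogate set would destroy the per-node spectra
  IAAFT is designed to preserve.
- Between-bin matrices are thresholded as ordinary graphs after
  symmetrization (the elementwise maximum of the two directed couplings),
  one OMST per matrix.
- Uncorrected p-values are reported alongside a Benjamini–Hochberg column;
  the hub-level inference itself is per node.

## Problem sizes used by the tests and acceptance script

The test-suite and `scripts/acceptance.R` exercise the full pipeline at
deliberately small scale, chosen so every stage (including the 100-surrogate
default) is representative while a complete run finishes in minutes: 2–4
bins at 80–210 Hz sampling, 4–16 nodes, 10–12 trials, 20–30 surrogates in
end-to-end runs (the `n_surrogates = 100` default is exercised in the null
calibration test), and 12-subject cohorts where the sign-flip enumeration
is exact. Oracle checks (DCI rebuild-from-scratch, OMST prefix
enumeration, single-layer PageRank) run on instances small enough for
exhaustive evaluation.

## Known limitations

- DCI is nonnegative by construction (removing a node cannot add interlayer
  edges), so per-subject DCI values are never symmetric around zero. The
  sign-flip test's symmetry null is therefore a pragmatic reference
  distribution rather than an exactly valid null at the pipeline level; its
  type-I calibration holds for symmetric inputs (which the test suite
  verifies) and the practical effect of the asymmetry is that candidates
  that are hubs in many subjects are easy to reject under it. Interpreting
  group p-values should keep this in mind.
- The z > 2 hub gate is tuned to fat-tailed centrality distributions over
  hundreds of nodes; small networks need a lower gate or will report no
  hubs (the pipeline then skips DCI with a notice).
- OMST's cost-efficiency objective is evaluated per matrix; no attempt is
  made to couple thresholding decisions across layers.
- The structural constraint is binary; streamline counts or weighted
  plausibility are not modelled.
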