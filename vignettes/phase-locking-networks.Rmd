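---
title: "Whole-brain phase-locking networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain phase-locking networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The method

plvnet implements an all-to-all, data-driven analysis of resting-state
functional connectivity for source-space electrophysiological recordings
(MEG-style data). The pipeline has four stages.

**1. Phase locking.** Each location's signal is decomposed with a complex
Morlet wavelet

$$w(t, f_0) = (\sigma_t \pi)^{-1/2}\, e^{-t^2/2\sigma_t^2}\, e^{2 i \pi f_0 t},$$

whose temporal and spectral bandwidths are tied by
$\sigma_f = 1/(2\pi\sigma_t)$ and by the constant spectral ratio
$f_0/\sigma_f = c$. The instantaneous phase $\theta(n)$ is the argument
of the wavelet coefficient at each sample, and the coupling between two
locations is the time-averaged phase locking value

$$\mathrm{PLV} = \frac{1}{N}\left|\sum_{n=1}^{N}
  e^{i(\theta_1(n) - \theta_2(n))}\right| \in [0, 1],$$

which is symmetric, amplitude-invariant, and 0/1 for random/fixed phase
relations. For $L$ locations the $L(L-1)/2$ unique pairs form a
symmetric, zero-diagonal adjacency matrix — the phase-locking graph.

**2. Dipole centrality.** The relative importance of each location is its
eigenvector centrality: the leading eigenvector of the adjacency,
oriented non-negative and normalized to unit Euclidean norm. High
scores mark dipoles connected to other well-connected dipoles.

**3. Functionally defined regions.** Vertices are clustered on the
standardized 4-D features (x, y, z, EVC) — each column z-scored — with a
k-means heuristic under cosine distance
$d(A,B) = 1 - A\!\cdot\!B / (\|A\|\|B\|)$. Centroids are data points:
after each mean update the centroid snaps to the member closest to the
mean. Spherically registered coordinates make the clusters spatially
smooth; the EVC column biases boundaries toward homogeneous
connectivity.

**4. Regional statistics.** For every unordered region pair the
dipole-level PLVs of the edges joining the two regions (resting
condition) are compared with the same edges computed from a signal-free
("empty-room"-like) recording, using a Monte-Carlo permutation test on
the difference of means. Pairs whose resting population exceeds the
null at level $\alpha$ form the significant region network.

A simplified minimum-norm inverse
$W = R A^{\mathsf T} (A R A^{\mathsf T} + \lambda^2 C)^{-1}$,
$\lambda^2 = 1/\mathrm{SNR}$, is included so that the dipole-pair
point-spread simulations can run end-to-end on synthetic spherical gain
matrices.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `c` | 7 | spectral ratio $f_0/\sigma_f$; at 10 Hz gives $\sigma_t \approx 111$ ms, $\sigma_f \approx 1.4$ Hz; at 30 Hz, 37 ms and 4.3 Hz |
| frequency grid | integer 5–40 Hz | analysis frequencies; bands (e.g. alpha 8–13 Hz) are entrywise averages of integer-frequency matrices |
| `k` | 40 | number of functionally defined regions; chosen from the dendrogram profile (see below) |
| `alpha` | 0.05 | per-pair significance level; no multiple-testing correction by default — the empirical null calibration shows the per-pair level is already honest |
| `minPerms` | 5000 | minimum Monte-Carlo permutations per pair |
| `stopTol` | 1e-4 | stop when the running p-estimate changes by less than 0.01% (relative) across a 500-permutation batch |
| `maxPerms` | 20000 | hard cap; the relative-change rule alone only triggers quickly for small p, so an explicit cap bounds cost for mid-range p |
| edge trim | $\lceil 3\sigma_t f_s\rceil$ samples | phase samples within three envelope standard deviations of either record end are discarded |
| `decimate` | 1 | optional phase-sample decimation before PLV averaging; valid because phase-difference processes are band-limited to a few Hz, so modest decimation leaves the estimate essentially unchanged |
| depth exponent | 0.8 | source-covariance weight $\|a_j\|^{-2\cdot 0.8}$ from gain column norms |
| tangential weight | 0.4 | orientation prior; tangential gain components scaled by 0.4, then only the normal component retained |

# Statistical design choices

**Sidedness.** The default test is one-sided (rest > null): a recording
made without a subject cannot contain genuine neuronal coupling, so only
excess phase locking is evidence of a connection. A two-sided variant is
available (`alternative = "two.sided"`).

**p-value estimator.** $p = (b+1)/(m+1)$, where $b$ of $m$ permuted
statistics are at least as extreme as the observed one. This never
returns $p = 0$ and is very slightly conservative, which the null
calibration confirms empirically.

**Stopping rule.** The Monte-Carlo loop runs at least `minPerms`
permutations and then stops when the running p-estimate moves by less
than `stopTol` (relative) over a 500-permutation batch, or at
`maxPerms`. We track the p-estimate — a functional of the permutation
distribution — rather than a binned histogram distance, which would
need an arbitrary bin width.

**Permutation unit.** Individual cross-region edge values, pooled over
subjects. Edges sharing a dipole are statistically dependent; the test
treats them as exchangeable anyway, and the empty-room calibration
(below) is the empirical check that this approximation leaves the
realized false-positive rate at the nominal level.

**Per-pair seeds** are drawn once from the master seed, so the network
is reproducible and independent of evaluation order. Optionally each
population can be subsampled to `maxEdges` values (seeded) to bound the
cost of very large region pairs.

# Clustering design choices

**Cosine distance.** The natural reading of the angular measure between
standardized feature vectors is a *similarity*; k-means needs a
distance, so the package minimizes $1 - $ similarity. Orthogonal
feature rows are at distance 1, antiparallel rows at 2.

**Snap-to-datapoint update with a monotonicity guard.** The mean of a
cluster followed by a snap to the nearest member is not guaranteed to
lower the within-cluster cost, so the snapped centroid is accepted only
when it does not increase that cluster's objective. With this guard the
global objective is non-increasing at every iteration (asserted in the
code) and convergence is guaranteed; without it the heuristic can
oscillate.

**Empty clusters** are repaired by reseeding them with the point
farthest from its current centroid, keeping the region count at exactly
k. **Restarts:** 10 random initializations by default, lowest objective
kept; all randomness flows from one seed. **Ties** in the snap step go
to the lowest vertex index.

**Dendrogram for choosing k.** The number of regions is a trade-off:
more regions mean more homogeneous clusters but quadratically more
permutation tests. `dendrogramProfile()` runs k-means once at a large
`kMax` and then agglomerates clusters by average-linkage cosine
distance, recording each merge's dissimilarity; k is chosen just below
the knee where merge dissimilarity rises sharply. Starting from
`kMax = L` the construction reduces exactly to average-linkage
agglomeration (verified against `hclust` in the tests). The default
k = 40 is used for both synthetic grid data and sphere-mesh data.

**Subject aggregation.** Adjacency matrices are averaged across subjects
first and a single centrality vector computed from the average
(`subjectCentrality(..., "adjacency")`). Averaging per-subject
centrality vectors instead is exposed as an option; for identical
inputs the two coincide.

**Degenerate geometry.** z-scoring a constant column is undefined;
planar grid scenarios therefore drop the constant z coordinate
(`buildFeatures(dropConstant = TRUE)`) and cluster on (x, y, EVC).

# Numerical choices

- Wavelet convolution is done by FFT with a discrete kernel truncated
  at $6\sigma_t$; the truncation ripple is $\sim e^{-18}$, and pure-tone
  phases are recovered to $\sim 10^{-5}$ rad (limited by record-edge
  leakage, not truncation). Only samples more than $3\sigma_t$ from the
  record ends are retained.
- Near-zero wavelet coefficients (magnitude below $10^{-12}\times$ the
  series RMS) trigger a warning rather than silent NaN phases; an
  all-zero signal is an error.
- The centrality solver uses the symmetric eigendecomposition rather
  than a literal SVD: on (near-)bipartite graphs the adjacency spectrum
  is symmetric about zero, the leading singular subspace is degenerate,
  and an SVD can return an arbitrary vector from that subspace. For
  symmetric non-negative matrices the leading eigenvector is the
  intended Perron vector; entries below $10^{-12}$ are clamped to zero
  and the sign is fixed by the largest-magnitude entry, making results
  deterministic across linear-algebra backends.
- The all-by-all PLV is computed from real trigonometric cross-products
  in row blocks; results are bit-independent of the block size.
- `SNR` in the inverse operator is interpreted as a power ratio
  ($\lambda^2 = 1/\mathrm{SNR}$).

# What the synthetic generators emulate

`nullGridScenario()` / the null datasets are iid unit Gaussian noise per
location — the idealization of an empty-room recording after whitening.
`gridScenario()` plants two square blocks whose cells share a sinusoid
$s_b(t) = A\,\sin(2\pi w_b t + \Phi_b(t)) + \varepsilon$ in a field of
iid noise, with four perturbations: the SNR multiplier, a low-frequency
modulator, per-sample phase jitter $\Phi(t) \sim U(-M, M)$, and a
frequency offset between the two blocks. `simulateDipolePair()` drives
two mesh vertices with equal-frequency sinusoids through a synthetic
spherical forward model and back through the minimum-norm inverse,
reproducing the point-spread phenomenology (spurious short-range
coupling around reconstructed sources) that motivates the FWHM-based
detection criterion.

**The modulator is additive by default.** The modulation condition asks
whether slow amplitude structure disturbs detection at the carrier
frequency. An additive low-frequency component is rejected entirely by
the analysis wavelet (its envelope at 20+ Hz away is essentially zero),
which matches the observed insensitivity of detection to modulators of
0.1–5 Hz. A multiplicative AM envelope $(1+\sin 2\pi f_m t)/2$ is also
available (`modType = "am"`); note it halves the in-band carrier power
and therefore *does* degrade detection — a property of that generator,
not of the analysis.

**Noise level and desk-scale operating point.** The full-scale study
conditions are 300 s records at a total SNR of −26 dB. Detectability of
a generator is governed by the ratio of its in-band phase coherence
$\rho^2$ to the PLV noise floor $\sqrt{\pi/4M_{\mathrm{eff}}}$, where
$M_{\mathrm{eff}} \approx T \cdot 2\sqrt{\pi}\sigma_f$ is the number of
effectively independent phase samples. Shortening T raises the floor,
so reproducing the full-scale signal-to-floor ratio on 8 s records
(the battery default) requires raising the SNR to about −17 dB; that
value is derived once from this matching argument, not fitted. The
battery's other reductions — a 30 × 30 grid with two 5 × 5 blocks,
phase decimation 6, population caps of 100 edges, a 6000-permutation
cap, 3 k-means restarts — are problem sizes chosen so the whole 4 × 4 ×
reps battery runs on a desk.

**What passing tests do not show.** The generators contain no 1/f
background, no spatially correlated sensor noise, no head geometry, no
artifacts, and (for the grid) no forward/inverse blurring, so the
synthetic calibration demonstrates the statistical machinery is honest
under its own assumptions — not that real recordings meet those
assumptions. Real-data preprocessing (artifact removal, tSSS, surface
extraction, coregistration) is out of scope.

# Known limitations

- **Frequency offsets and time-averaged PLV.** When the two blocks run
  at different frequencies (say 25 vs 20 Hz) the phase difference
  rotates at the 5 Hz beat, and its time average cancels like
  $|\mathrm{sinc}(\Delta f\, T)|$ — for any $\Delta f \gg 1/T$ the
  inter-block PLV sits at (in fact slightly below) the noise floor.
  Consequently the detection rate at a 20 Hz offset is
  indistinguishable from the 1 Hz offset under this estimator: both are
  at chance. A time-windowed PLV could in principle distinguish nearby
  offsets within the wavelet bandwidth; windowed estimators are out of
  scope here.
- **Edge dependence.** Edges sharing a dipole are dependent; the
  permutation test ignores this. The empty-room calibration shows the
  realized false-positive fraction stays near alpha at the study
  conditions, but strongly structured dependence (e.g. heavy inverse
  smoothing with tiny regions) could move it.
- **Point generators and the EVC feature.** A single-vertex generator
  pair concentrates centrality on two distant vertices; after
  z-scoring, those two outlying EVC values can dominate the cosine
  distance and merge the generators into one (spatially disjoint)
  region. Extended sources — the realistic case, and the grid blocks —
  do not do this. The contiguity report (`contiguityReport()`) makes
  such degeneracies visible.
- k-means favors clusters of similar spatial extent and the dendrogram
  knee under-estimates the "true" number of regions; regions mixing
  more than one functional population inflate type II error, not type
  I.

# Reproducing the study conditions

```{r, eval = FALSE}
library(plvnet)

## calibration of the statistical pipeline on signal-free data
nc <- nullCalibration(nPairs = 10, alpha = 0.05, nLocations = 200,
                      duration = 60, fs = 250, f0 = 10, c = 7, k = 40,
                      seed = 1)
nc$mean   # fraction of the 780 region pairs declared significant

## grid perturbation battery at desk scale
battery <- perturbationBattery(reps = 10, seed = 1)
batteryTPR(battery)
```

`scripts/acceptance.R` runs exactly these computations (plus the wavelet
bandwidth and PLV landmark values) from a single seed and writes the
results as JSON.
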