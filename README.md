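# plvnet — whole-brain phase-locking connectivity networks

plvnet is an R package for data-driven, all-to-all functional
connectivity analysis of resting-state source-space recordings
(MEG-style dipole time series). It is aimed at researchers who want
whole-brain network estimates without pre-specifying regions of
interest, together with the synthetic validation machinery needed to
trust those estimates.

## The method

For every pair of the *L* cortical locations, coupling at an analysis
frequency *f₀* is measured by the time-averaged **phase locking value**

> PLV = (1/N) |Σₙ exp(i(θ₁(n) − θ₂(n)))| ∈ [0, 1],

where the instantaneous phases θ come from a complex **Morlet wavelet**
w(t, f₀) = (σₜπ)^{−1/2} e^{−t²/2σₜ²} e^{2iπf₀t} with bandwidths tied by
σ_f = 1/(2πσₜ) and the constant ratio f₀/σ_f = c (default c = 7; at
10 Hz: σₜ ≈ 111 ms, σ_f ≈ 1.4 Hz). The L(L−1)/2 values form a weighted
graph from which each dipole's **eigenvector centrality** is computed.
Vertices are then clustered into k spatially coherent **functionally
defined regions** by k-means with cosine distance on the standardized
(x, y, z, centrality) features, and every region pair is tested against
a signal-free ("empty-room") recording with a one-sided Monte-Carlo
**permutation test** on the difference of mean edge PLVs (≥ 5000
permutations, p = (b+1)/(m+1), α = 0.05). The result is the graph of
significantly connected regions at the chosen frequency or band.

A simplified minimum-norm inverse W = RAᵀ(ARAᵀ + λ²C)^{-1}, λ² = 1/SNR
(depth weighting 0.8, tangential weighting 0.4), and a family of seeded
synthetic generators (grid perturbation scenarios, dipole-pair
point-spread scenarios, signal-free nulls) let the entire pipeline be
validated end-to-end with no external data. See the methods vignette
(`vignettes/phase-locking-networks.Rmd`) for models, parameter
defaults, and design choices.

## Worked example

Plant two 10 Hz generators on a 100-vertex sphere mesh, add unit
Gaussian noise everywhere, and run the full pipeline against a
signal-free null dataset:

```r
library(plvnet)

makeWaveletSpec(10, c = 7)
#> Morlet WaveletSpec: f0 = 10 Hz, c = 7, sigma_f = 1.429 Hz, sigma_t = 0.1114 s

dir <- tempfile(); fx <- makeFixtures(dir, seed = 1, duration = 20)
res <- runPipeline(list(rest = fx$rest, null = fx$null1,
                        geometry = fx$mesh, freqs = 10, k = 10,
                        minPerms = 5000, seed = 1,
                        outDir = file.path(dir, "out")))
res$plvRest
#> PLVMatrix (10 Hz): 100 x 100, off-diagonal range [0.000, 0.954], mean 0.097
res$parcellation
#> Parcellation: 100 vertices in 10 regions (objective 15.9633, 6 iterations)
res$network
#> RegionNetwork: 10 regions, 45 pairs tested, 6 significant at alpha = 0.05

sig <- subset(networkEdges(res$network), significant)
head(sig[order(sig$p), ], 3)
#>    regionA regionB   observed            p nPerms significant
#> 35       5      10 0.02893937 0.0000499975  20000        TRUE
#> 6        1       7 0.01985591 0.0092495375  20000        TRUE
#> 34       5       9 0.03834625 0.0099987502   8000        TRUE

parcelLabels(res$parcellation)[fx$generators]
#> [1] 5 9
```

The two planted generators land in regions 5 and 9, which the
permutation network declares significantly connected (p ≈ 0.01); the
strongest edge (5–10) joins a generator region to its spatial
neighborhood, the short-range coupling that regularized source
reconstructions are known to induce and that the package's FWHM-based
scoring (`computeFwhm()`, `scoreDetection()`) accounts for. All outputs
(PLV matrices, centrality, parcellation, edge-list TSV and GraphML) are
written to `outDir` with JSON metadata.

A thin command-line front end is included at `inst/scripts/plvnet`
(subcommands `plv`, `band`, `evc`, `parcellate`, `pipeline`,
`fixtures`).

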