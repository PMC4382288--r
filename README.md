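# filamentnoise

Noise and spatial-correlation analysis of gene expression along
one-dimensional cell filaments.

In filamentous cyanobacteria, periodic developmental patterns (such as
nitrogen-fixing heterocysts) emerge from fluctuations in the expression of a
master regulator along a chain of cells. Quantifying those fluctuations
requires statistics defined on the filament as a 1D lattice: this package is
for microscopists and systems biologists who measure per-cell fluorescence
of a reporter along filaments and want to know **how noisy** expression is,
**how far** fluctuations in neighbouring cells are coupled, and whether
bright cells **cluster** more than independent cells would.

## What it computes

For a set of filaments with per-cell fluorescence `F(1..L_f)`:

* **Noise** — the squared coefficient of variation `σ_p²/μ_p²` over all
  cells, and its decomposition into between-filament and within-filament
  components (`population_noise()`, `noise_decomposition()`).
* **Spatial autocorrelation** on the cell lattice,

  ```
  g(n) = ⟨ (1/(L_f−n)) Σ_m (F(n+m)−μ_f)(F(m)−μ_f) / σ_f² ⟩_filaments ,
  ```

  with the negative estimator bias (μ_f estimated from the same short
  series) compensated by within-filament position permutation
  (`autocorrelation_corrected()`), plus the nearest-neighbour scatter view
  and its Pearson coefficient (`neighbor_pairs()`).
* **Histogram comparisons** on shared bins: Earth Mover's Distance
  `EMD = Σ_i |CDX(i)−CDY(i)|`, Kolmogorov–Smirnov distance
  `D_KS = max_i |CDX(i)−CDY(i)|`, and the two-sample statistic
  `X² = (1/MN) Σ_i (M n_i − N m_i)²/(n_i+m_i)` with χ²(b−1) p-values;
  bootstrap standard errors (`emd()`, `ks_distance()`, `cluster_chi2()`,
  `bootstrap_se()`).
* **Cluster statistics** — binarize each population at its upper-15%
  quantile, collect run lengths of contiguous supra-threshold cells, and
  compare against the independent-cell Bernoulli null (1000 strings of 20
  cells, p = 0.15), whose finite-string run-length law is available in
  closed form (`binarize()`, `cluster_sizes()`,
  `simulate_bernoulli_strings()`, `bernoulli_run_length_law()`,
  `compare_to_independent()`).
* **Synthetic data** — a trace generator with controlled between-filament
  heterogeneity and a moving-average spatial kernel (analytic
  autocorrelation returned alongside), and a microscopy-like image renderer
  with ground-truth labels (`generate_traces()`, `generate_images()`).
* **Segmentation** — adaptive-threshold cell recognition (global Otsu,
  iterative local re-thresholding of oversized components), ordering of
  cells into filaments along the centroid chain graph, and per-cell mean
  fluorescence extraction (`segment_cells()`, `order_into_filaments()`,
  `extract_fluorescence()`).
* **Pipeline** — an end-to-end, YAML-configurable, deterministically seeded
  driver writing CSV/JSON/TIFF artifacts and a manifest (`run_pipeline()`,
  `validate_config()`; thin CLI wrapper in `inst/scripts/`).

## Worked example

```r
library(filamentnoise)

sim <- generate_traces(trace_gen_params(n_filaments = 100, seed = 42))
sim$set
#> filament_set: 2445 cells in 100 filament(s), 1 run(s)
#> filament lengths: 8-40 (median 25)

population_noise(sim$set)       # squared CV over all cells
#> 0.103
noise_decomposition(sim$set)
#> noise decomposition over 100 filaments:
#>   between = 0.02174  within_avg = 0.0832  ratio = 0.261

autocorrelation_corrected(sim$set, n_max = 4, seed = 42)
#> correlation curve (bias-corrected), 100 filament(s)
#>   n        g   g_raw     bias        se
#> 1 0  1.00000  1.0000  0.00000 1.127e-17
#> 2 1  0.54399  0.4878 -0.05617 2.090e-02
#> 3 2  0.19858  0.1480 -0.05060 2.304e-02
#> 4 3 -0.13692 -0.1965 -0.05962 2.606e-02
#> 5 4 -0.09546 -0.1511 -0.05569 2.800e-02

bf <- binarize(sim$set)                    # upper-15% threshold
compare_to_independent(all_cluster_sizes(bf), seed = 42, n_boot = 1000)
#> EMD = 0.7566 +/- 0.106
```

Reading: per-cell noise is ≈ 0.10, about a quarter of which traces to
between-filament heterogeneity (`ratio = 0.26`). The corrected
autocorrelation decays over two to three cells — the generator's MA(2)
kernel at work; the `bias` column shows the negative estimator bias
(≈ −1/(L−1)) that the permutation shuffles estimate and remove. The
cluster-size distribution of supra-threshold cells sits 0.76 bin units of
EMD away from what independent cells would produce: bright cells cluster.

The same analysis runs end to end from a config:

```r
run_pipeline(demo_config(seed = 1, output_dir = "demo_out"))
# -> cells.csv, curves.csv, noise.json, clusters.json, manifest.json
```

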