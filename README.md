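# tdfe — tensor-decomposition-based unsupervised feature extraction

`tdfe` selects outlier genes from **multi-way gene expression designs** —
experiments indexed simultaneously by tissue, treatment, and further
condition axes — without using class labels in the selection statistic.
It is aimed at transcriptomics studies where the question is not "which
genes differ between two groups" but "which genes follow a particular
combination of condition patterns", e.g. genes differentially expressed
between stressed and control animals *and* coexpressed across a specific
subset of tissues.

## The method

Standardized expression is arranged as a dense tensor
`x[i, j1, ..., jm]` (gene `i`, condition levels `j1..jm`) and decomposed
by full higher-order singular value decomposition (HOSVD):

    x[i, j1, ..., jm] = Σ over (ℓ1, ..., ℓm, ℓg) of
        G(ℓ1, ..., ℓm, ℓg) · u_g[i, ℓg] · Π_k u_k[jk, ℓk]

where each factor matrix `u_k` holds the orthonormal *singular value
vectors* of mode `k` (left singular vectors of that mode's unfolding)
and `G` is the all-orthogonal core tensor whose large-magnitude entries
mark which vector combinations dominate the data.

Analysis proceeds in three steps:

1. **Identify condition vectors of interest** — e.g. the treatment-mode
   column with opposite signs over control/treated (a treatment
   difference), or a tissue-mode column loading a target tissue subset
   (`find_contrast_vector()`).
2. **Choose gene vectors Ω coupled to them** by ranking core entries
   with those condition indices fixed (`choose_omega()`, `rank_core()`).
3. **Score and select genes.** Each gene gets
   `S_i = Σ_{ℓ∈Ω} (u_g[i, ℓ] / σ_ℓ)²` with `σ_ℓ` the standard deviation
   of vector ℓ over genes; under the null of standard-normal
   standardized components, `S_i ~ χ²` with `|Ω|` degrees of freedom.
   Upper-tail P-values are Benjamini–Hochberg adjusted and genes with
   adjusted P below a threshold (default 0.01) are selected.

The package also ships:

* a fully specified **synthetic benchmark** (`synthetic_spec()`,
  `generate_synthetic()`, `run_benchmark()`): 30,000 genes × 10 tissues
  × 10 treatments, ten planted sets of 100 genes each expressed
  (`N(4,1)` vs `N(0,1)` background) in 4 of 10 tissues under one
  treatment, every sample standardized — with TPR/FPR/AUC scoring and
  cluster-recovery evaluation (Ward and Gaussian-mixture clustering in
  singular-vector space, `cluster_genes()` / `confusion_table()`);
* a **GEO Series Matrix pipeline** for the GSE68077 murine stress study
  (`parse_series_matrix()`, `filter_probes()`, `standardize_samples()`,
  `assemble_tensor()`, `run_ptsd_analysis()`, `ttest_combinations()`)
  building the five-mode tensor genes × treatment(2) × tissue(10) ×
  stress duration(2) × rest period(3), with replicate averaging and
  zero-filled unobserved cells;
* a **command line** (`tdfe_cli()`; script in `inst/cli/tdfe`) with
  subcommands `simulate`, `decompose`, `select`, `geo-pipeline`,
  `ttest`, staged artifacts and YAML run manifests.

Results are tibbles (or carry `tidy()` / `glance()` methods) and plot
via `autoplot()` / `plot_factor()`.

## Worked example

```r
library(tdfe)

spec  <- synthetic_spec(seed = 1)          # the 30,000-gene benchmark
bench <- run_benchmark(spec, n_trials = 3)
bench
#> <td_benchmark> 3 trials, 30000 genes
#> # A tibble: 3 × 5
#>   method threshold   tpr       fpr n_selected
#>   <chr>      <dbl> <dbl>     <dbl>      <dbl>
#> 1 BH          0.01 0.972 0.0000345       973.
#> 2 BH          0.05 0.994 0.000276       1002
#> 3 BH          0.1  0.996 0.000701       1017.
#> mean AUC: 1
```

At BH threshold 0.01 the pipeline recovers 97% of the 1,000 planted
genes with a false-positive rate of 3.5·10⁻⁵ (about one background gene
per 30,000), and the χ² statistic ranks planted above background genes
essentially perfectly (AUC ≈ 1). Clustering the selected genes in the
space of the first ten gene singular value vectors recovers the planted
sets almost one-to-one — each row (true set) concentrates in a single
cluster column:

```r
bench$confusion$ward
#>             cluster
#> set           1  2  3  4  5  6  7  8  9  10 11
#>   set1       94  0  0  0  0  0  0  0  0   0  0
#>   set2        0 54 43  0  0  0  0  0  0   0  0
#>   set3        0  0  0 98  0  0  0  0  0   0  0
#>   ...
#>   background  0  0  0  0  0  0  0  0  1   0  0
```

(Cutting the Ward tree at 11 clusters with ten real groups typically
splits one set in two, as for set 2 here; the Gaussian-mixture variant
selects the number of components by BIC and returns the ten sets
directly.)

For a real study, the same machinery runs from a Series Matrix file:

```r
geo <- parse_series_matrix("GSE68077_series_matrix.txt")
expr <- geo$expression |> filter_probes(prefix = "EA") |> standardize_samples()
tensor <- assemble_tensor(expr, geo$design)
res <- run_ptsd_analysis(tensor, threshold = 0.01)   # l1/l2 auto-identified
tidy(res)            # per-probe statistic and P-values
ttest_combinations(expr, geo$design, selected_genes(res$selection))
```

`run_ptsd_analysis()` locates the treatment-difference vector and the
tissue vector coexpressed in amygdala, hippocampus and heart, fixes
both in the core ranking, and selects probes from the three gene
vectors most strongly coupled to them. Downloading the GEO series is
deliberately manual: the package never touches the network.

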