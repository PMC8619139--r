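# photonet

Prioritization of photosensitizer compound families in untargeted LC-MS²
metabolomics.

Extracts of pigmented organisms can be *photocytotoxic*: inert in the dark,
strongly cytotoxic under visible light. The active principles — e.g.
anthraquinone pigments in certain *Cortinarius* mushrooms — are a handful of
light-absorbing metabolites hidden among thousands of LC-MS features.
photonet finds them by triangulating three independent lines of evidence
onto a feature-based molecular network (FBMN):

- **Structure**: a molecular network from MS² spectra, using the modified
  cosine — fragment pairs match directly (|Δm/z| ≤ τ) or shifted by the
  precursor mass difference, weights are products of √-scaled intensities,
  and the score is the maximum-weight one-to-one assignment normalized to
  [0, 1]. GNPS-style topology filters (score ≥ 0.7, ≥ 6 matched peaks,
  mutual top-10 rank, component size cap 100) produce clusters of putative
  compound families.
- **Chromophore**: the *VIS-Signal* flag — a feature is marked `1` when a
  DAD absorbance peak at a visible wavelength (468 nm) co-elutes with it at
  S/N ≥ 3 in at least one extract (only absorbed light can photosensitize).
- **Bioactivity**: extract-level photoactivity — relative singlet-oxygen
  yield from DMA (9,10-dimethylanthracene) photobleaching kinetics,
  100·k_sample/k_control, plus four-parameter Hill EC50 fits
  v(c) = b + (t − b)/(1 + (c/EC₅₀)^h) with censoring at the top tested dose
  and selectivity indices S.I. = EC₅₀,dark / EC₅₀,irradiated.

A cluster's priority is the number of its features that are simultaneously
VIS-positive and specific (area share > 0.99) to a photoactive extract. A
deterministic synthetic-data generator with planted ground truth (analog
families, species-specific abundances, chromophore DAD peaks, Hill-shaped
dose-response with censored dark conditions) makes the whole pipeline
testable offline.

## Worked example

Generate the default synthetic study (six extracts, 91 features in 15
planted families, 61 of them chromophore-bearing and extract-specific) and
run the full pipeline:

```r
library(photonet)
cfg    <- generator_config(seed = 1)
bundle <- file.path(tempdir(), "bundle")
generate_bundle(cfg, bundle)
summary <- run_pipeline(from_bundle(bundle, out_dir = file.path(tempdir(), "out")))
print(summary)
#> photonet run summary
#>   spectra read: 91, nodes: 91, edges: 250, clusters: 15, singletons: 0
#>   VIS-positive features: 61, candidate features: 61
#>   active extracts: rubrophyllus, xanthophyllus
#>   top clusters (id: priority): 1: 12, 2: 8, 3: 8, 4: 7, 5: 7
```

All 91 spectra joined the quant table and formed 15 clusters — exactly the
planted families. 61 features carry a VIS-Signal, and all 61 are specific to
one of the two extracts the assay stage flagged active, so they survive the
candidate filter. The top-ranked cluster is the planted 12-analog
anthraquinone-like family:

```r
head(summary$clusters, 3)
#>   cluster_id n_nodes n_vis_positive n_active_specific priority rank
#> 1          1      12             12                12       12    1
#> 2          2       8              8                 8        8    2
#> 3          3       8              8                 8        8    3
```

`run_pipeline()` also writes Cytoscape-ready artifacts to `out_dir`:
`network.graphml`, `node_attributes.tsv` (m/z, RT, VIS flag, per-extract
shares, cluster id, annotations), `clusters.tsv`, `candidates.tsv`, and a
machine-readable `summary.json`.

The dose-response machinery works standalone. Fitting a noise-free curve
with EC50 = 1.6 µg/mL on the standard six-dose ladder, against a dark
control with no measurable toxicity (censored at the 37.5 µg/mL top dose):

```r
d   <- c(37.5, 18.75, 7.5, 3.75, 1.875, 0.375)
fit <- fit_hill(d, 100 / (1 + (d / 1.6)^1.5), c_max = 37.5)
print(fit)
#> Hill fit: EC50 = 1.6 ug/mL (95% CI 1.6-1.6), slope 1.50
selectivity_index(censored_ec50(37.5), fit)
#> S.I. >= 23.4
```

The "≥" marks the index as a lower bound (dark EC50 censored); 23.4 means
at least a 23-fold potency gain under irradiation for this cell line.

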