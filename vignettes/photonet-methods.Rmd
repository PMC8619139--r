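---
title: "Methods: photosensitizer prioritization from molecular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photosensitizer prioritization from molecular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonet)
```

## The problem

Crude extracts of pigmented organisms (here, the running example is a set of
six *Cortinarius* mushroom extracts) can be photocytotoxic: harmless in the
dark, strongly cytotoxic under visible light. The active principles are
usually a handful of light-absorbing secondary metabolites — e.g.
anthraquinone pigments — buried among thousands of LC-MS features. photonet
codifies a prioritization strategy that triangulates three independent lines
of evidence onto untargeted LC-MS² data:

1. **Structural relatedness** — a feature-based molecular network (FBMN)
   groups features whose MS² spectra share fragments, directly or shifted by
   the precursor mass difference, into candidate compound families.
2. **Chromophore evidence** — the *VIS-Signal* flag: a feature only qualifies
   as a photosensitizer candidate if a DAD peak at a visible wavelength
   (default 468 nm) co-elutes with it (first law of photochemistry: only
   absorbed light can act).
3. **Biological evidence** — extract-level photoactivity: relative singlet
   oxygen yield from DMA photobleaching kinetics, and light-dependent
   cytotoxicity (Hill-fit EC50s, selectivity indices).

A network cluster is prioritized by how many of its members are
simultaneously VIS-positive and specific to a photoactive extract.

## Spectral similarity and network construction

The modified cosine between spectra $A$ and $B$ with precursor difference
$\Delta = m_B - m_A$ admits a fragment pair $(i, j)$ when
$|m_{A,i} - m_{B,j}| \le \tau$ (direct) or
$|m_{A,i} - (m_{B,j} - \Delta)| \le \tau$ (shifted), with
$\tau = 0.02$ Th by default. Pair weights are products of square-root-scaled
intensities; a one-to-one assignment is chosen greedily by descending weight
(ties broken by peak index), and the assigned weight sum is normalized by the
product of the $\ell_2$ norms of the square-root intensity vectors, giving a
score in $[0, 1]$ that is symmetric in its arguments. The greedy rule is
cheap and, on the small candidate sets real spectra produce, agrees with the
exhaustive maximum-weight assignment — the test suite checks this against a
brute-force oracle on a fuzz battery of small spectra.

Graph construction follows GNPS conventions: edges require score
$\ge 0.7$ and $\ge 6$ matched peaks; an edge survives only if both endpoints
rank it within their top 10 incident edges; oversized components
(> 100 nodes) are split by repeatedly removing their weakest edge (ties by
lexicographic endpoint ids, components relabelled after each removal). All
five parameters are arguments of `build_network()` and pipeline-config keys,
because the "right" values are data-dependent and published networks rarely
state them.

## Specificity and the VIS-Signal

A feature's share in extract $e$ is its LC peak area there divided by its
summed area over all extracts. Specificity levels use strict inequalities —
`>0.60` (major occurrence), `>0.95` (virtual), `>0.99` (complete
specificity) — and all-zero features are excluded as degenerate.

The VIS-Signal flag scans every extract's DAD trace at the feature's
retention time. Within ±0.1 min the *window mean* absorbance is compared to
a local baseline (median of the surrounding ±0.5 min, window excluded); the
noise scale is the MAD (×1.4826) of that baseline region, and the flag is 1
when the best signal-to-noise ratio across extracts reaches 3 — the
conventional detection limit. Two deliberate choices:

* The window **mean** is used rather than the window maximum. The maximum of
  ~20 noise samples is biased upward by nearly two noise standard deviations,
  which at threshold 3 produces a substantial false-positive rate on
  chromophore-free features; the mean of the window has noise reduced by
  $\sqrt{n}$ and still captures a peak whose width (sd 0.05 min) is
  comparable to the window.
* Evidence is taken as the **best across extracts**, because a feature gets
  one flag per network node, and the extract where the feature is abundant is
  where its chromophore is detectable.

A consequence, faithful to how such workflows behave in practice, is that
genuinely colored but low-abundance features stay at flag 0 — their DAD peak
is below the noise floor.

## Photoactivity quantification

**Radiant exposure** is irradiance × time: the default light sources deliver
1.24 J cm⁻² min⁻¹ (blue, 468 nm) and 1.34 J cm⁻² min⁻¹ (green, 519 nm), so
7.5 min blue = 9.3 J cm⁻² and 15 min green = 20.1 J cm⁻².

**DMA assay.** Singlet oxygen bleaches 9,10-dimethylanthracene; its
absorbance at 377 nm is read at t = 0 and after four irradiation cycles. The
bleaching rate $k$ is the negative slope of the least-squares line of
$A_{377}$ versus cumulative irradiation time (blank drift subtracted when a
blank series is provided; blank replicates are averaged before
interpolation). The relative yield is $100 \cdot k_{sample}/k_{control}$
against the light source's positive control (berberine for blue, rose bengal
for green), so values above 100% are possible. The slope-ratio definition is
a pluggable strategy: it reproduces the assay's comparative semantics
without committing to a specific published calibration formula, is invariant
under a common absorbance rescaling, and returns exactly 100% for the
control against itself. Replicates are fitted separately; the yield standard
error is propagated from the replicate slope errors by the delta method.
The ascorbate co-incubation wells are summarized as a diagnostic
"protection" fraction $1 - k_{DMA+AA}/k_{DMA}$ (a reducing quencher
intercepts radical chemistry, so high protection hints at a Type I
contribution); it feeds no downstream decision.

**Dose-response.** Viability (% of control) is fitted with the
four-parameter Hill model
$v(c) = b + (t - b) / (1 + (c/EC_{50})^{h})$
by Levenberg–Marquardt least squares (`minpack.lm`), with $EC_{50}$
parameterized on the log scale. Starting values are $t = 100$, $b = 0$,
$h = 1$, $EC_{50}$ at the geometric mid-dose, with perturbed restarts on
non-convergence. Because viability is expressed in percent of an untreated
control, the plateaus are bounded a priori ($t \in [50, 150]$,
$b \in [-50, 50]$); without these bounds, ladders that never sample the
upper plateau (a potent extract whose lowest dose already kills) let $t$ and
$EC_{50}$ run away together. If the fitted curve has not crossed 50%
viability anywhere in $(0, c_{max}]$, the result is censored at the top
tested dose ($c_{max} = 37.5$ µg/mL for the standard ladder
37.5, 18.75, 7.5, 3.75, 1.875, 0.375 µg/mL) and reported as
"> $c_{max}$". The 95% CI is the Wald interval on $\log EC_{50}$ (t
quantile, residual df), back-transformed — the standard asymmetric interval
dose-response software reports.

The pipeline fits one curve per extract × cell line × light on the pooled
replicate points rather than averaging per-replicate fits: with a 6-dose
ladder a single-replicate fit retains 2 residual degrees of freedom and is
numerically fragile, while the pooled fit uses all 18 points.

**Selectivity and classification.** The selectivity index is
$S.I. = EC_{50,dark} / EC_{50,irradiated}$; when the dark EC50 is censored
the index is a lower bound (reported "≥"). Potency bands on the EC50:
> 20 µg/mL no/low, 5–20 µg/mL (both ends inclusive — the boundary
convention is stated because the verbal rule leaves 5 and 20 ambiguous)
high, < 5 µg/mL very high.

## Integration

An extract is *active* when its DMA yield reaches the 5% floor (yields below
that are indistinguishable from the assay's blank variation) on any light
source, or any irradiated EC50 classifies high/very high. A cluster's
priority is the number of member features that are VIS-positive **and**
specific (share > level, default 0.99) to an active extract; ranking is by
priority, ties by VIS-positive count, then cluster id, and priority-0
clusters stay unranked. The same conjunction, ungrouped, yields the
candidate feature list per extract. The default level 0.99 (complete
specificity) is configurable — the choice of level trades recall against the
risk of chasing features shared with inactive extracts.

## Annotation

Dereplication reuses the modified cosine against a user-supplied spectral
library; shifted matching lets one library spectrum catch methylated
(+14.0157), oxidized (+15.9949), glycosylated (+162.0528) and chlorinated
(+33.9610) analogs. Identification levels follow the common 1–4 confidence
scheme: level 1 is reserved for marker compounds of known identity whose
precursor also matches; every other accepted hit is level 2. Taxonomically
informed re-ranking adds configurable boosts (defaults: species 0.20, genus
0.10, family 0.05 on the [0, 1] cosine scale) for every rank at which a
candidate's source taxonomy matches the sample's — a deliberately simple,
transparent stand-in for more elaborate published weighting schemes, kept
configurable. Marker identities propagate to all members of the marker's
network component, encoding the structural-relatedness assumption of
molecular networking.

## The synthetic study

`generator_config()` fixes a complete, ground-truth-labeled study emulating
the data structure the analysis assumes; `generate_bundle()` writes it in
every input format. Defaults, chosen once as the reference conditions:

* **Six extracts**, two photoactive (a *Dermocybe*-like "rubrophyllus" and a
  *Phlegmacium*-like "xanthophyllus") and four inactive — labels are
  cosmetic.
* **15 compound families** (91 features): nine chromophore-bearing,
  extract-specific families — 9 features planted > 99%-specific to
  rubrophyllus and 52 to xanthophyllus, the largest single family (12
  analogs) being the designated photoactive anthraquinone-like family — plus
  six chromophore-free background families. Each family owns a scaffold of
  8–15 fragments in an m/z band disjoint from every other family's, so
  between-family similarity is ≈ 0 by construction; analogs shift the
  precursor and a fixed substitution-site subset of fragments by one
  derivatization mass, with log-normal intensity jitter (sdlog 0.15).
* **Retention times** on a 0.5-min grid: adjacent chromatographic peaks
  (sd 0.05 min) are then baseline-resolved, so the local-median baseline of
  the VIS detector sees at most modest contamination from neighbors.
* **Peak areas**: planted-specific features get exactly 99.5% of their total
  area in the target extract; others draw Dirichlet shares leaning toward
  their majority extract, capped below the 0.99 level.
* **DAD traces** at 468 nm, 0.01-min sampling, Gaussian baseline noise
  (sd 0.5 mAU), chromophore peaks at 30× noise amplitude in the feature's
  majority extract.
* **DMA kinetics**: exponential decay with the control at 0.006 min⁻¹ — every
  series, including samples bleaching ~1.8× faster than the control, stays
  in the initial-slope regime where the linear-slope estimator is accurate,
  while the total signal change remains well above the 0.001 AU read noise;
  technical duplicates, five reads (t = 0 plus four cycles of 5 min blue /
  4.6 min green). True yields mirror the motivating study's pattern (two
  strongly active extracts near 123%/184% under blue light, inactive
  extracts below 5%).
* **Dose-response**: the standard ladder in biological triplicate, Gaussian
  viability noise sd 5%; dark conditions use a true EC50 of 200 µg/mL, far
  beyond the top dose, so their fits censor by design.

Everything is a deterministic function of (seed, config): the same seed
yields byte-identical bundles and pipeline summaries.

**What passing on this generator does and does not show.** The generator
reproduces the *statistical skeleton* of real data — family structure with
analog shifts, species-specific abundances, chromophore/DAD coupling,
censored dark toxicity. It does not simulate co-eluting isomers, adduct or
isotope networks, retention-time drift between runs, heteroscedastic or
drifting DAD baselines, matrix effects on ionization, or inner-filter
effects in the DMA assay. Tests passing here validate the algorithms and
their integration, not performance on any particular instrument's output.

## Numerical conventions and degenerate inputs

* Retention times in minutes, m/z in Thomson, CSV decimal separator "."; MGF
  charge defaults to −1 (negative ionization mode).
* Empty spectra are legal everywhere; two empty spectra score 0 without
  error. Zero-total-area features are degenerate: all shares 0, excluded
  from specificity counts.
* Greedy-assignment ties break by smaller (index_a, index_b); edge-removal
  ties during component splitting break by lexicographic endpoint ids —
  every ranking the package emits is deterministic.
* A flat or rising DMA control raises an "inactive positive control" error
  rather than returning a negative yield; ascorbate protection with a
  non-positive DMA rate is reported missing.
* Problem sizes in the shipped tests and the acceptance script — 91-feature
  bundles, 200-pair similarity fuzz, 500-fit dose-response simulation — were
  chosen as the smallest sizes at which the statistical claims (ARI,
  bias/coverage, exact planted counts) are meaningful.

## Known limitations

* One representative MS² spectrum per feature is assumed (as FBMN's upstream
  provides); no spectral merging or ion-identity networking.
* The VIS flag is binary; no λmax estimation or spectral deconvolution.
* The DMA yield is relative, not an absolute singlet-oxygen quantum yield;
  no inner-filter or spectral-overlap correction is attempted.
* The linear-slope bleaching-rate estimator attenuates rates as total decay
  grows (a sample bleaching twice as fast as the control does not show
  exactly twice the fitted slope); at the generator's operating point the
  resulting understatement of the largest yields is a few percent.
* In silico candidate lists and chemical-taxonomy tables are consumed, never
  computed.
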