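---
title: "Individual morphological brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual morphological brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A subject's morphological network treats atlas regions as nodes and the
statistical similarity between regional gray-matter (GM) intensity
distributions as edges. Given a VBM-preprocessed (segmented, normalized,
modulated, smoothed) GM volume and an integer-labeled parcellation on the
same voxel grid, the pipeline is:

1. **Nodes.** Atlas regions (typically 90, paired across hemispheres).
   Labeled voxels with no GM in their 2-mm cubic neighborhood are removed
   (`refine_atlas()`), mirroring the standard mask-refinement step that
   strips white-matter voxels from an anatomical atlas.
2. **Regional densities.** Each region's voxel intensities form a sample;
   its probability density function is estimated by Gaussian kernel
   density estimation with Scott's-rule bandwidth
   \(h = \hat\sigma\, n^{-1/5}\) (`estimate_pdf()`).
3. **Edges.** For regions with densities \(p, q\), the symmetric
   Kullback–Leibler divergence
   \(KL(p,q) = \int p \log(p/q) + q \log(q/p)\,dx\)
   is mapped to a similarity \(KLS(p,q) = e^{-KL(p,q)} \in [0,1]\),
   with 1 for identical distributions. All unordered region pairs give an
   \(R \times R\) similarity matrix per subject; the diagonal is stored
   as `NA` and never analyzed.
4. **Binarization.** A sparsity threshold \(S\) retains the
   \(K = \mathrm{round}(S \cdot R(R-1)/2)\) strongest pairs, so every
   subject's graph has identical node and edge counts. The sweep default
   is 10%–40% in 1% steps with a spotlight at 23%.
5. **Graph metrics.** Clustering coefficient \(C_p\), characteristic path
   length \(L_p\), global and local efficiency \(E_g, E_{loc}\), and
   normalized betweenness \(b_i = B_i / \mathrm{meanBet}\). Small-world
   ratios \(\gamma = C_p / C_p^{rand}\), \(\lambda = L_p / L_p^{rand}\),
   \(\sigma = \gamma / \lambda\) are computed against degree-preserving
   (Maslov edge-swap) null ensembles, 100 references by default.
6. **Cohort analyses.** Mean and coefficient-of-variation connection
   maps; hubs (nodes whose cross-subject mean \(b_i\) exceeds the
   across-node mean by more than one sample SD); betweenness-profile
   similarity (mean Pearson correlation with the other subjects) and
   uniqueness (1 − maximal correlation), rescaled to [0, 1];
   test–retest reliability by one-way random-effects ICC(1,1), edge-wise
   and metric-wise; and Pearson/Spearman correlation of each metric with
   a covariate (age), FDR-corrected over the 8-metric family at the
   spotlight threshold and deliberately uncorrected across the sweep.

## Numerical choices

* **Common grid per pair.** KL needs shared support. For each region
  pair the two KDEs are evaluated on one 256-point grid spanning the
  pooled samples ± 3 bandwidths. Doubling to 512 points moves KLS by
  less than 1e-3 (enforced in tests). A global grid would be cheaper but
  wastes resolution on pairs with narrow supports.
* **Density floor.** Densities are floored at 1e-12 then renormalized,
  so the log-ratio integrand stays finite where one tail underflows.
  A consequence worth knowing: once two distributions stop overlapping,
  KL saturates near the floor-driven maximum and KLS stops responding to
  further separation.
* **Two engines.** The pairwise kernel exists in pure R
  (`estimate_pdf()` + `kls()`) and as compiled code (default); they agree
  to ~1e-7 (the compiled path truncates the Gaussian kernel at 8
  bandwidths, far below the floor) and the test suite compares them
  directly.
* **Ties and rounding at the cutoff.** \(K = \mathrm{round}(S\,R(R-1)/2)\);
  ties at the cutoff value are broken by lexicographic (row, column)
  order so runs are bit-reproducible.
* **Disconnected graphs.** \(L_p\) averages over reachable pairs only and
  attaches a `morphnet_disconnected` warning, keeping low-sparsity
  networks computable while flagging them; \(E_g\) counts unreachable
  pairs as zero efficiency, its conventional limit.
* **Betweenness.** Fractional shortest-path counting (Freeman/Brandes),
  endpoints excluded; on a complete graph all \(B_i = 0\) and the
  normalized profile is undefined (`NA`) rather than silently zero.
* **Maslov rewiring.** 10 attempted double-edge swaps per edge, seeded
  per (subject, threshold, replicate); degree sequence and edge count are
  preserved exactly by construction, and a stall (e.g. rigid graphs)
  warns with the achieved swap count.
* **ICC.** One-way random effects, single measurement — ICC(1,1) =
  (MSB − MSW)/(MSB + (k−1)MSW) — matching the variance-ratio definition
  of reliability; negative raw estimates are clamped to 0 for reporting
  with the raw value retained. Bands: ≥ 0.75 excellent, 0.59–0.75 good,
  0.40–0.58 fair, else poor. The reported p is the one-way ANOVA F-test.
* **Gray-matter threshold in refinement.** "Gray matter" is GM > 0 on
  the modulated map by default, exposed as `gm_threshold`; voxels valued
  exactly 0 inside retained regions stay in the sample unless
  `exclude_zero = TRUE`.

## The synthetic cohort generator

`synthetic_spec()` / `generate_cohort()` produce atlas-labeled volumes
whose regional intensities are drawn from truncated-at-0 normal
distributions. The stated world:

* **Homotopic pairs.** Regions come in hemisphere pairs sharing a
  generating distribution, emulating the high inter-hemispheric
  similarity of real GM maps. Pair means are spread 0.30–2.94 in steps
  of 4 within-region SDs (SD 0.015), so that generator families are
  separated well beyond KDE sampling noise at the default 500 voxels per
  region: the 45 same-generator pairs are recoverable as the top-45 KLS
  edges.
* **Subject effects.** Location shifts (SD 0.015) and scale effects
  (SD 0.003, 20%) act at the pair level — a subject's anatomy moves both
  hemispheres together. The scale effects matter: for region pairs whose
  means are far apart the KL integral saturates at the density floor and
  location shifts carry no between-subject signal there; within-region
  spread differences do, and are what makes edge-wise ICC high across
  the whole matrix.
* **Sessions.** Each session redraws the voxel sample and adds a
  per-region location perturbation (SD 10% of the between-subject SD).
  With the perturbation set to 0, sessions are exact replicas. Voxel
  resampling is itself a realistic source of within-subject noise and is
  the main ceiling on edge-wise ICC.
* **Age effect.** The covariate is min-max rescaled to [0, 1] and
  inflates every region's scale by up to 45% at the oldest age,
  *one-sidedly from the youngest subject's baseline*. The reason for
  this parameterization is a genuine property of KLS networks that we
  measured while designing the generator: a uniform multiplicative
  inflation rescales all pairwise divergences by a common factor, so the
  edge *ranking* — and hence the thresholded topology — changes only
  through the fixed-size KDE sampling noise, whose relative weight grows
  with the inflation. A two-sided (z-scored) effect therefore produces
  no consistent trend, while one-sided inflation yields the expected
  monotone degradation: clustering and local efficiency decline with age
  (r ≈ −0.5 at most thresholds in the acceptance cohort).
* **What a green test does not establish.** The generator is stylized:
  contiguous block regions rather than cortical geometry, unimodal
  truncated normals rather than real VBM intensity mixtures, no partial
  voluming or scanner artifacts, and narrower within-region spread than
  real modulated GM maps. Green acceptance tests establish that the
  estimator chain recovers known structure, reliability and injected
  covariate effects in this world — not that real Kirby21 values are
  reproduced; those remain external benchmarks requiring the MRI data
  and an SPM/VBM stack.

## Known limitations

* Weighted-network analytics on raw KLS values are out of scope; all
  metrics assume binary undirected graphs.
* No spatial resampling: volumes and atlas must share a voxel grid
  exactly.
* The NIfTI-1 reader/writer covers the common single-file subset
  (uint8/int16/int32/float32/float64, optional gzip, scl slopes); it
  does not reorient, and NIfTI-2/ANALYZE files are rejected.
* Exhaustive oracle verification of the graph metrics runs over all
  graphs on ≤ 5 nodes plus random 6- and 8-node graphs; full 6-node
  enumeration is possible but exceeds the default test-time budget.
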