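---
title: "Methods: early-integration trend comparison of omics dataset pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early-integration trend comparison of omics dataset pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendtide)
```

## The model

trendtide compares how gene abundances change across a set of ordered
conditions in two quantitative omics datasets at a time. The unit of
analysis is the *trend*: a cluster of per-gene profile shapes. The pipeline
is deliberately simple and fully deterministic given a seed:

1. **Load.** Each dataset is a genes × conditions matrix of pre-normalized
   abundances. Genes with any missing cell are dropped (and reported), not
   imputed — the method assumes complete profiles, and inputs in this domain
   are typically averaged over replicates upstream.
2. **Per-gene statistics.** Variance and median abundance across conditions
   are computed on the *raw* values, together with their percentile ranks
   over the dataset's gene universe. These ranks drive all filters.
3. **Z-score.** Each gene's profile is centered and scaled within its
   dataset: `(x − mean) / sd_pop`. This removes per-gene location and scale
   so that only profile *shape* matters, which is what makes trends
   comparable between, say, FPKM and log2-LFQ units.
4. **Partition.** Genes present in both datasets (by exact, case-sensitive
   ID; an opt-in flag uppercases IDs) are *intersecting*; the rest are
   *non-intersecting* and clustered separately per dataset, which also keeps
   the joint clustering balanced when one dataset is much larger.
5. **Early integration.** The z-profiles of the intersecting genes of both
   datasets are stacked into one 2n × c matrix and clustered with k-means++
   into k trends. Each gene thus receives two labels in one shared label
   space; equal labels mean the same centroid, so a gene is *concordant*
   iff its labels agree.
6. **Sankey model.** Nodes = (dataset, trend) gene sets; links = the
   (trend_A, trend_B) intersections, at most k² of them. The model obeys
   conservation laws (node size = Σ incident link sizes; Σ link sizes =
   number of intersecting genes; concordant count = Σ diagonal links) that
   the acceptance suite checks on random synthetic inputs.
7. **First-level filters.** Percentile-range filters on variance or median
   abundance (single- or both-dataset scope) and a minimum link size subset
   the model *without reclustering*: trend identities must stay fixed while
   the user explores ranges, otherwise the objects under discussion would
   change mid-exploration. The pre-clustering variance filter, by contrast,
   runs before step 5 and does change the clustering.
8. **Second-level enrichment.** Gene sets picked from nodes or links are
   tested per GO term with a two-sided Fisher's exact test on the 2×2 table
   (selected × in-term) over a background, with Benjamini–Hochberg FDR.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 4 | number of trends, 2–10; chosen by the user, not optimized automatically |
| `seed` | — | one integer drives all clustering runs (joint, only-A at seed+1, only-B at seed+2) and, in sessions, pair *i* at seed+10(i−1) |
| `n_init` | 10 | k-means++ restarts; lowest inertia kept |
| `max_iter`, `tol` | 300, 1e-6 | Lloyd iteration cap and centroid-shift convergence threshold |
| filter `lo`, `hi` | 0, 100 | percentile range in [0,100]; a gene survives iff its rank ∈ [lo, hi] |
| `alpha` | 0.05 | FDR significance threshold for enrichment |

## Numerical conventions

These were genuinely open choices; each is pinned so results are
reproducible, and none is load-bearing for the qualitative behavior:

* **Population standard deviation** (divisor n) in the z-score and in the
  per-gene variance. Any consistent choice works; this one avoids a special
  case at two conditions.
* **Zero-variance genes** z-score to the all-zero profile and are *kept*
  (flagged in a report); the variance filter is the sanctioned mechanism for
  removing flat genes.
* **Percentile ranks** use midpoint averaging for ties:
  `100 · (rank_avg − 1)/(n − 1)`, spanning exactly [0, 100]; they are
  invariant under monotone transforms of the metric. Ranks are computed once
  on the loaded data and kept global — dynamic filters do not re-rank the
  surviving subset, so filter compositions stay set-algebraic.
* **Canonical trend labels.** k-means labels are arbitrary, so after
  fitting, clusters are relabeled by descending centroid value at the first
  condition (ties broken by the following conditions). This gives stable
  label identities and colors across reruns.
* **Empty-cluster repair** reseeds an empty cluster at the point farthest
  from its centroid — a standard Lloyd fix-up; with n_init = 10 restarts it
  is rarely exercised.
* **Fisher's exact test** is computed by hypergeometric enumeration: the
  two-sided p-value sums the probabilities of all tables no more probable
  than the observed one, with a 1e-7 relative tie tolerance. This matches
  `stats::fisher.test` to 1e-10 (tested on 100 random tables) while keeping
  the implementation independent of the oracle it is tested against.
* **BH-FDR** is applied within each GO category separately by default
  (mirroring per-category reporting conventions of GO tools); a flag
  switches to one global correction. Direction (over/under) is observed vs
  expected count, `expected = n_selected · n_term / n_background`.
* **Percentages** keep full precision internally and are rounded to one
  decimal only at presentation.
* The **custom clustering file** has no canonical schema in the field; this
  package uses a long format `(gene, dataset, condition, value, cluster)`
  because a single file then carries both profiles and labels, and arbitrary
  label alphabets are mapped bijectively onto `0..k−1`.
* The **single-dataset filter scope**, applied to a pair, retains a gene
  that passes the range in at least one dataset; `both_datasets` requires
  both — equal, by construction, to the intersection of the per-dataset
  survivor sets.

## What the synthetic generator emulates — and what it does not

`generate_pair()` plants `n_trends` shape prototypes (piecewise-linear:
increasing, decreasing, peak, dip, then shifted variants) over the condition
axis, populates each (trend_A, trend_B) cell with a chosen number of genes,
adds i.i.d. Gaussian noise in shape space, and maps each dataset through its
own affine transform to raw units (defaults emulate FPKM-like and
log2-LFQ-like scales: ×100+500 and ×2+20). Noise is added *before* the
affine map so that per-gene z-scoring must genuinely invert the scale
difference — recovery therefore tests the whole normalization + clustering
chain, not just k-means. Defaults (4 trends, 20 genes per cell, noise sd
0.2, 10% non-intersecting per side, 6 conditions) describe a small but
realistic desk-scale comparison; shapes must stay separated by more than
4·noise_sd or the spec is rejected.

The generator does **not** emulate replicate structure, count-level noise
(negative binomial), batch effects, correlated noise between the two
datasets of a gene, or missingness. A green recovery test therefore
establishes that the pipeline recovers well-separated mean-shape structure
under independent Gaussian perturbation — not that it is robust to the full
noise anatomy of real experiments. Conversely, the conservation and
determinism criteria are exact properties and hold regardless of the noise
model.

Per-gene z-scoring maps a planted shape s to `(s − mean(s))/sd(s)` with the
divisor inflated by the noise variance, so recovered centroids approximate
`(s − mean(s))/sqrt(var_pop(s) + noise_sd²)`; the tests compare against this
corrected expectation.

## Degenerate inputs and edge behavior

* Disjoint gene sets → "nothing to compare" error at the stacking step.
* `k` above the row count, or outside [2, 10] → error.
* A selection empty after background intersection, or a background smaller
  than the selection → error; selection genes missing from the background
  are dropped with a warning.
* Terms with zero members are dropped at annotation load with a warning.
* FDR = 0 is clamped to the smallest positive double before `−log10`, for
  plotting only.
* Highlight IDs absent from the data are reported, never fatal.

## Known limitations

* k-means favors spherical clusters in z-space; strongly unbalanced or
  non-convex trend families may be split or merged (density-based
  alternatives are out of scope here).
* `k` is user-chosen; there is no automatic model selection.
* Non-intersecting genes have per-dataset label spaces that are *not*
  comparable across datasets; they never enter the Sankey model.
* GO enrichment does not propagate annotations along the GO graph and does
  not reduce term redundancy; the annotation file is taken at face value.
* All I/O is local; no identifier mapping or online resources.
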