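---
title: "Glycopattern analysis of lectin microarrays: model, normalization and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycopattern analysis of lectin microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycolect)
```

## The assay and the quantity being modeled

A lectin microarray probes the glycan repertoire ("glycopattern") of a
protein sample without releasing the glycans: a slide is spotted with a
panel of carbohydrate-binding proteins (lectins), each with a known glycan
specificity — SNA binds Sia2-6Gal/GalNAc, ConA binds high-mannose
N-glycans, and so on. Fluorescently labeled sample proteins bind each
lectin in proportion to how strongly their glycans match, and a scanner
reports per-spot foreground and background median intensities.

`glycolect` implements the downstream analysis for the canonical replicate
design of such experiments: a panel of 37 lectins, printed as three
continuous spots per lectin within a block, three blocks per slide, three
slides per group — nine replicate blocks per group in total. The
biological sample per group is a pool, so all replication is technical.

## Normalization: NFI and its compositional consequences

Per block, each spot's local background estimate is subtracted from its
foreground median (values floored at 0, since a normalized signal fraction
cannot be negative), and the replicate median per lectin is taken. The
median of each lectin is then divided by the sum of all lectins' medians
in that block, giving the **normalized fluorescence intensity (NFI)**:

$$\mathrm{NFI}_{l,b} \;=\; \frac{m_{l,b}}{\sum_{k} m_{k,b}},
\qquad \sum_l \mathrm{NFI}_{l,b} = 1 .$$

Group profiles are the mean ± sample SD of a lectin's NFI over the nine
blocks. Because NFIs are fractions, they are invariant to any global
scaling of a block's intensities — slide brightness, laser power and
labeling efficiency cancel — which is why NFI ratios between groups are
comparable at all without inter-slide normalization.

The closure $\sum_l \mathrm{NFI}_l = 1$ has a second, less convenient
consequence: a *raw* fold change $f$ on one lectin's binding shifts every
other lectin's NFI downward. If lectin $l$ has baseline NFI weight $w$ and
its raw signal is multiplied by $f$ while all others stay fixed, the
observable NFI ratio is not $f$ but

$$ r \;=\; \frac{f}{1 + (f-1)\,w}, $$

approaching $f$ only as $w \to 0$ (generally
$r_l = f_l \sum_k \mu_k / \sum_k f_k \mu_k$ for per-lectin baselines
$\mu_k$ and folds $f_k$). `expected_nfi_ratio()` exposes this closed form,
and the simulator plants effects on raw net intensity — not on NFI —
precisely so that this distortion is explicit and testable.

## Differential calling

For a model-vs-control contrast, each lectin gets the ratio of group mean
NFIs. A ratio **≥ 1.5** calls the glycan up-regulated and **≤ 0.67**
down-regulated, both thresholds inclusive; everything between is
unchanged. The field also reports a two-sample **Student's pooled t-test**
on the block-level NFIs (9 vs 9 blocks). Choices made here, where the
conventions in published work are ambiguous:

* **p-gate.** The default gate requires $p < 0.05$ *in addition to* the
  fold-change threshold (`p_gate = "lt"`). Published descriptions of this
  kind of analysis sometimes print the opposite inequality, which we read
  as a typographical slip; both alternative readings are available
  (`p_gate = "gt"` / `"off"`). The bundled reference tables are
  reproduced with the fold-change gate alone, since only ratios — not
  replicate data — were published.
* **Down threshold.** 0.67 (≈ 1/1.5) is the default; the occasional 0.66
  variant changes no call in the bundled tables and is configurable.
* **Student's, not Welch's t**, because that is what the design names;
  `welch = TRUE` is available. With nine technical replicate blocks per
  group and pooled samples, the equal-variance assumption is mild.
* **No multiple-testing correction by default**, matching the
  fold-change-centred convention of the assay; Benjamini–Hochberg is
  available (`fdr = "bh"`).
* **Degenerate variance.** Zero pooled variance with equal means gives
  $t = 0, p = 1$; with unequal means $p = 0$ plus a warning (this arises
  in noise-free simulations, not in real data).

Cross-model comparison collapses a model's (possibly multi-timepoint)
calls to one direction per lectin — *significant at any timepoint* counts,
and a lectin both up and down across timepoints is "mixed". *Shared*
lectins are significant in both models; *opposite* lectins are shared with
strictly opposite directions (mixed never qualifies). The motif summary
tokenizes the opposite lectins' specificity strings into monosaccharide
symbols (GalNAc, GlcNAc, Gal, Glc, Man, Fuc, Sia) with longest-match
semantics, so GalNAc is never also counted as Gal; matching is
case-insensitive so "High-Mannose" counts as Man.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates spot tables with the full replicate
geometry and known ground truth:

```
fg = min(saturation, net · spot_noise · block_eff · slide_eff + bg)
```

* `spot_noise` is log-normal with coefficient of variation `spot_cv`
  (default **0.1**), mean-corrected to 1;
* `block_eff` and `slide_eff` are shared log-normal batch multipliers
  (log-scale SDs **0.05** each) — multiplicative batch structure is the
  standard error model for fluorescence arrays;
* background is additive truncated-normal (mean **100**, SD **20** a.u.)
  and the actual added background is also reported as the spot's local
  background estimate, i.e. the scanner's local background estimation is
  assumed unbiased;
* baseline net intensity defaults to a uniform **1000 a.u.** per lectin
  (roughly mid-range for a 16-bit scanner after background), saturation to
  **65535 a.u.**, and spots are flagged bad with probability **0.01**.

The published study states no variance components, so these defaults are
package choices calibrated to what is typical for spotted fluorescence
arrays, documented here once and not tuned against any test outcome. The
simulator does **not** model spot morphology, spatial gradients within a
block, dye chemistry, or carry any biological between-animal variance
(the design pools samples) — so a green simulation-based test establishes
that the pipeline recovers planted compositional effects under realistic
technical noise, not that it would overcome artifacts the model omits.

## Numerical and design choices

* Background mode: the wording "subtracting the average background" is
  ambiguous between per-spot local background (the GenePix convention,
  our default) and a block-wide mean (`bg_mode = "block-mean"`). The two
  agree exactly when background is spatially flat.
* Median of an even number of surviving replicates is the midpoint of the
  two central values; flagged spots are excluded before the median.
* A lectin with no surviving spot in a block is marked missing, excluded
  from that block's normalization sum, and averaged over the blocks where
  it is present; a block with every spot flagged, or with all-zero net
  medians, is an error rather than a silent NA.
* Clustering (for the heat-map report) defaults to 1 − Pearson
  correlation across groups with average linkage — the common choice for
  expression heat maps; the published figure states neither. The
  agglomerative merge is deterministic with ties broken by panel order,
  and pairs involving a constant column fall back to Euclidean distance
  (their correlation is undefined). Heat-map cells are column z-scores
  ("expression relative to the rest of the column"); a numeric sidecar
  TSV of exactly the plotted values is always written because the image
  itself is not a testable artifact.
* The default panel's 14 non-published positions are filled from a
  documented registry of common lectins and are explicitly marked
  `source == "registry"`; they are placeholders, not a claim about the
  original array layout, and fully overridable via `read_panel()`.

## Known limitations

* The raw fluorescence scans behind the bundled reference ratio tables
  were never deposited, so the headline mean NFIs themselves cannot be
  recomputed; everything derivable from the printed ratios (counts,
  directions, cross-model sets) is reproduced exactly, and the pipeline's
  arithmetic is validated on simulated ground truth instead.
* NFI ratios inherit compositional distortion (see above): a lectin can
  appear "down" purely because another lectin's signal rose. The package
  reports the distortion's closed form but does not attempt a
  compositional (e.g. log-ratio) reanalysis, which would not be
  comparable to the published thresholds.
* The t-test treats the nine blocks as independent; blocks within a slide
  share a batch multiplier, so the test is mildly anticonservative under
  strong slide effects. This mirrors the published design rather than
  correcting it.
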