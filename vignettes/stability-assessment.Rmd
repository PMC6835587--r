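---
title: "Assessing storage-condition stability of metabolites in direct-infusion MS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing storage-condition stability of metabolites in direct-infusion MS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimstab)
```

## The problem

Untargeted metabolomics of biofluids such as cerebrospinal fluid (CSF) is
increasingly used to search for small-molecule biomarkers, and the cohorts
assembled for such searches are rarely uniform: aliquots differ in how many
times they were thawed and in how long they sat at −20 °C, in a fridge
(5–8 °C) or at room temperature (18–22 °C) before final storage at −80 °C.
If storage shifts metabolite levels by more than the assay's own
variability, those shifts masquerade as biology.

`dimstab` implements a complete assessment of this question for
direct-infusion mass spectrometry (DIMS) data. In DIMS there is no
chromatography: each feature is an m/z peak, each sample is characterised by
a called peak list per infusion, and a metabolite "annotation" is a named
mass matched to peaks within a tight relative tolerance. The package covers
annotation, internal-standard QC, fold-change classification, and a
per-feature statistical battery, together with a synthetic-data generator
that emulates the underlying study design so that every stage can be
validated against known ground truth.

## The study design being modelled

The reference design is: `P = 3` biofluid pools; per pool one *reference*
aliquot (frozen at −80 °C at time zero) plus 22 storage conditions spanning
four series — freeze/thaw cycles 1–7, storage at −20 °C for 1–4 months, at
5–8 °C for 8–168 h, and at 18–22 °C for 2–168 h; and `R = 3` technical
replicates (repeated infusions of one preparation) per sample. That yields
`3 × 23 = 69` samples and 207 infusions.

The exact 22-condition grid is a reconstruction — the published design is
described only through its extremes and a handful of interior levels — so
`default_condition_grid()` is plain data and any grid with strictly
increasing, unique levels per series is accepted. Failed infusions are
modelled by an `excluded` flag: excluded rows stay in the sample sheet but
contribute to no statistic, mirroring runs in which a few of the 69 samples
are lost.

## Annotation model

Five singly charged ion species are considered per neutral metabolite:
[M+H]⁺, [M−H]⁻, [M+Na]⁺, [M+K]⁺ and [M+Cl]⁻, with monoisotopic shifts
(+1.007276, −1.007276, +22.989222, +38.963158, +34.969401 Da) that include
the electron mass. A peak at m/z $x$ matches the channel with theoretical
m/z $t$ iff $|x - t|/t \times 10^6 \le 2$ ppm. Choices fixed here:

* **Inclusive boundary.** "Within 2 ppm" is a window; we make the boundary
  inclusive so behaviour at exactly 2 ppm is defined and testable. At
  `tol_ppm = 0` only exact theoretical values match.
* **Isomers are kept.** A peak may match several metabolites (or several
  peaks one channel); all matches are retained and summed into their
  respective annotations. DIMS cannot separate isomers, and the bundled CSF
  panel deliberately contains formula-duplicate pairs.
* **One value per annotation per sample.** Matched intensities are summed
  over the five channels (missing channels contribute zero, with a
  `detected` flag) and technical replicates are then collapsed by the
  arithmetic mean (median by option). Downstream statistics always operate
  on these collapsed values, so pools — not infusions — are the replication
  unit.
* **Scan window.** Peaks outside 70–600 m/z are dropped at ingestion with a
  logged count; no intensity normalisation is ever applied.

## Analysis variability from internal standards

Spiked stable isotope-labelled compounds (sILC) are chemically inert to
storage history — whatever variation they show is assay variation. Two
scales are computed:

* **CV** per sILC: sample standard deviation over mean (n−1 denominator; the
  convention is stated because published tables rarely say) across all
  included samples.
* **MAV** per sILC and series: for the most extreme level of the series,
  per-pool fold change against the reference, minus 1, absolute value,
  median across pools. The per-series MAV used by the classifier is the
  median of these over all sILCs.

Summaries report the 5th percentile, median and 95th percentile over
compounds. The quantile rule is configurable (`type =` of
`stats::quantile`): published percentile rows are sensitive to the
interpolation convention and could not be pinned to any common rule, so the
package treats percentiles as method-dependent and only the median (which is
an exact order statistic for odd n under every common rule except pure ECDF
interpolation) as reproducible.

Note a subtlety of the median-of-three construction: MAV is zero whenever a
*majority* of pools sit exactly at fold change 1, not only when all do. It
is a robust location estimate, not a supremum.

## Fold-change classification

For metabolite $i$, series $s$, level $\ell$ and pool $p$, the fold change
is $FC_{ip} = I_{ip}(s,\ell) / I_{ip}(\mathrm{ref})$. Across the $n \le 3$
pools with a usable reference (positive, not excluded) the package computes
a 95% interval and calls the metabolite:

* `increased` if the lower limit $> 1 + \mathrm{MAV}_s$;
* `decreased` if the upper limit $< 1 - \mathrm{MAV}_s$;
* `unaffected` otherwise; `undefined` if fewer than two pools remain
  (undefined records are excluded from affected counts and tallied).

Inequalities are strict: "above the band" means above. The default interval
is the t-interval around the mean,
$\bar{FC} \pm t_{0.975,\,n-1}\, s/\sqrt{n}$. The source analyses are
ambiguous about whether the centre was a mean or a median across three
pools; their figure legend plots the mean, so the mean-based t-interval is
the default here, and a `minmax` method (observed range) is provided for
sensitivity analysis. With n = 3 the t multiplier is 4.30 — the interval is
wide, which is precisely why a handful of null metabolites straying outside
a narrow band is expected behaviour rather than a defect, and why the
affected counts are labelled "possibly affected".

sILC entries are never classified: they calibrate the band. Counts
(`count_affected()`) are reported for the full annotation set and for the
neurometabolic panel subset, at the most extreme level per series by
default, matching how such results are usually tabulated.

## Statistical battery

* **Repeated-measures ANOVA** per feature, across the reference plus every
  level of a series, pools as subjects:
  $F = MS_{cond} / MS_{cond \times subj}$ with $(k-1)$ and $(k-1)(n-1)$
  degrees of freedom, no sphericity correction (none is assumed by the
  analyses this mirrors). Implemented as explicit sums of squares for speed
  over thousands of features; the test suite cross-checks it against
  `aov(y ~ cond + Error(subject))` and against the paired-t² identity at
  two levels. Incomplete pools are dropped with a message; an all-equal grid
  returns F = 0 flagged degenerate rather than 0/0.
* **Kruskal–Wallis** comparing the most extreme level to the reference on
  pool-level values (3 vs 3 by default), mid-rank tie correction, χ²₁
  reference. With 3 vs 3 the statistic has only 20 permutation atoms and the
  χ² p-value bottoms out near 0.0495; after Bonferroni correction over a
  ~1850-feature family such a test can *never* reject. The package keeps the
  test because its null results are informative jointly with the others, and
  documents the discreteness here.
* **Bonferroni** with explicit family size `m` (all features, or 106-scale
  for a panel), `min(1, m·p)`.
* **PCA** over samples, mean-centring only by default (consistent with "no
  normalisation"); unit-variance scaling by option.

## The synthetic-data generator

`simulate_peak_tables()` produces peak lists in which metabolite $i$ in
pool $p$ under condition $c$ at replicate $r$ has total intensity

$$ I = b_i \cdot g_p \cdot d_i(c) \cdot e^{\varepsilon},\qquad
   \varepsilon \sim N(0, \sigma^2), $$

split across the five adduct channels by fixed per-metabolite weights, with
uniform m/z jitter (default ±0.5 ppm, safely inside the matching window)
and optional per-channel dropout. Choices and rationale:

* **Multiplicative lognormal noise** because intensities are positive and
  observed assay CVs are scale-free. A single infusion's CV is
  $\sqrt{e^{\sigma^2}-1}$.
* **Default σ = 0.29.** Triplicates share the preparation (drift and
  baseline) and differ only by infusion noise, so the cross-sample CV of
  triplicate-averaged sILC intensities is ≈ σ/√3. σ = 0.29 puts that CV
  near 0.17, the scale reported for this assay type; the package's own QC on
  a default-world run reproduces that order (the worked example in the
  README prints 0.177). Tests that state their own noise level (0, 0.07,
  0.15) pass it explicitly.
* **Drift-free internal standards.** The generator refuses drift
  specifications that touch sILC entries — by construction their fold change
  to reference is exactly 1 at σ = 0.
* **Unambiguous libraries.** `generate_library()` separates every adduct
  channel of every pair of metabolites by more than twice the matching
  tolerance (per polarity), slightly stronger than separating neutral
  masses, so that synthetic matches are provably unique unless collisions
  are wanted (use the bundled panel for the isomer case).

What the generator does **not** emulate: per-sample preparation noise shared
across triplicates (only infusion noise exists, so replicate averaging buys
back √3 of precision, which real prep noise would not allow), drift over
injection order, batch structure, isotope envelopes, peak-shape artefacts,
intensity-dependent noise, and missingness correlated with abundance. A
green test on synthetic data therefore establishes that the *computational
pipeline* recovers known truth under its stated noise model — not that the
assay itself behaves this way.

## Numerical and degenerate-input conventions

* Zero or missing reference intensity: that pool's fold change is dropped
  (logged); fewer than two pools ⇒ `undefined`, excluded from counts.
* All-zero intensity vectors make the CV undefined: an error, not NaN.
* `classify_call` at exactly the band edge returns `unaffected` (strict
  comparisons).
* All-tied Kruskal–Wallis input returns H = 0, p = 1 (the library routine
  would return NaN from the tie-correction 0/0).
* Determinism: every stochastic routine takes a seed (`withr::with_seed`,
  so the caller's RNG state is untouched) and `run_pipeline()` writes
  byte-identical output bundles for identical config + seed.
* Config files are JSON; the run manifest embeds the full configuration, so
  a bundle is regenerable from its manifest alone.

## Limitations

With three pools the fold-change interval has two degrees of freedom, so
power is low and the classifier is intentionally conservative in both
directions; the reference aliquot itself has undergone one freeze/thaw
cycle in the emulated design, so "cycle 1 vs reference" contrasts are not
interpretable as "first thaw" effects; and the bundled panel library is a
curated convenience fixture (masses computed from molecular formulas,
including isotope-label shifts for the 17 sILCs), not an authoritative
database extract.
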