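---
title: "Methods: probe remapping, chemotype quantification and cascade flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe remapping, chemotype quantification and cascade flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `vitiflora`, the
assumptions they make, the parameters worth knowing about, and the design
choices taken where more than one defensible option existed.

## 1. Probe-to-gene remapping

### The problem

Terpene synthases form a large, recently duplicated gene family, so probes
designed against one generation of grapevine gene models often
cross-hybridize with several curated *VviTPS* models. Any gene-level
expression statement built on such probes is unreliable unless the
ambiguity structure is known.

### The matching rule

A probe is mapped to a gene model iff the *full-length* probe aligns
ungapped at some offset with Hamming distance ≤ `max_mm` (default 2). Both
the probe and its reverse complement are scanned (`orientations =
"forward"` restricts this). The scan is exhaustive and exact:

* At ≤ 2 mismatches over a short oligo, no gapped alignment can satisfy a
  full-length rule, so an exhaustive Hamming scan is not an approximation
  of a heuristic homology search — it is the complete answer to the stated
  criterion, and it is oracle-testable against a naive double loop.
* `N` and other IUPAC degeneracy codes count as mismatches wherever they
  occur, even against themselves. A degenerate base cannot support a
  confident hybridization call; the conservative rule is also
  deterministic.
* Multiple placements of one probe within one gene collapse to a single
  (probe, gene) entry at the minimal mismatch count; ties break by smaller
  offset, then forward orientation before reverse complement. Counts are
  therefore independent of input order.
* Coordinates are 0-based and half-open internally and in files; rendered
  reports use 1-based positions.

Probes hitting exactly one model are *unique*; probes hitting two or more
are *ambiguous* with ratio `1:n`; the rest are *unmapped*. These three sets
always partition the probe universe. Gene-level expression is the
arithmetic mean of the unique probes' values per sample, on the log2
(RMA-like) scale on which the values arrive — genes covered only by
ambiguous probes are reported as dropped rather than imputed.

Whether a historical homology-search protocol scanned both strands, or how
it collapsed multi-placement hits, is generally not recoverable from
published methods sections; the explicit rules above are this package's
own, so exact agreement with any particular published probe count is a
validation goal, not a guarantee.

## 2. Expression clustering and hotspot detection

Clustering uses Euclidean distance and average linkage by default
(`metric`, `linkage` configurable), matching common clustered-heatmap
defaults. Correlation distance refuses constant rows by name rather than
silently producing `NA`s. Missing values are rejected, not imputed: RMA
matrices are complete by construction, so a missing value indicates an
upstream problem.

`detect_hotspots()` turns "draw a square on the heatmap" into an
algorithm:

1. **Robust z-scores.** Each gene row is median-centered and divided by a
   pooled robust sigma — the median over genes of the per-row scaled MAD.
   Two deliberate deviations from a textbook per-row z-score: (a) a
   mean/sd row z-score has an algebraic ceiling (≈ 1.2 for a block
   covering 5 of 12 samples, regardless of effect size), which would put
   the default threshold of 1.5 permanently out of reach; (b) even the
   per-row MAD is inflated by the hotspot cells themselves when the block
   spans a sizeable minority of samples. Pooling the scale over all rows
   is safe because most rows are background.
2. **Seeding.** Rows and columns of the z matrix are clustered (Euclidean,
   average linkage) and each dendrogram is cut at the largest gap between
   consecutive merge heights. Every (row cluster × column cluster) pair
   seeds a candidate block.
3. **Refinement.** Each candidate is refined by alternating optimal
   two-group splits (minimum within-group sum of squares) of the in-block
   minus out-of-block contrast scores on each axis until stable. A raw
   dendrogram cut routinely clips or pads a block by one member; the
   refinement step is what makes recovered boundaries exact. The contrast
   (rather than the plain in-block mean) removes the residual bias the
   row-median centering leaves on block rows.
4. **Reporting.** Refined blocks with mean z ≥ `z_threshold` (default 1.5)
   and at least `min_genes` × `min_samples` cells (default 2 × 2) are
   deduplicated and reported sorted by mean z.

The detector is a stated heuristic for a construct that is usually drawn
by eye; all thresholds are surfaced as arguments and echoed in the report.
Raising `z_threshold` never increases the number of reported blocks.

## 3. Volatile quantification and chemotype statistics

* **Calibration** (`fit_calibration`): ordinary least squares of the
  response ratio (analyte area / internal-standard area) on the standard
  amount (µg in the extraction vial). The intercept is free by default —
  forcing the line through the origin is stricter than headspace data
  usually supports — and `through_origin = TRUE` is available.
* **Quantification** (`quantify`): `max(0, (ratio − b)/a) / mass` in µg/g
  fresh weight. Negative back-calculated amounts clamp to zero and are
  flagged (`clamped`); physically, concentrations cannot be negative, and
  keeping the flag preserves auditability. Compounds without their own
  authentic standard use the designated fallback curve — classically the
  (+)-valencene curve — and are flagged `semi-quantitative`.
* **Composition** (`composition`): per-sample percentages over a stated
  compound class. Green-leaf aldehydes and alkanes are excluded from
  sesquiterpene compositions simply by not being in the class argument.
  All-zero samples have no defined composition; they are excluded and
  recorded, never silently zero-filled.
* **Group comparisons** (`relative_change`): arithmetic means of replicate
  concentrations, no outlier removal; `100 (m_a − m_b)/m_b` so "A relative
  to B" reads as its sign suggests.
* **PCA** (`pca_chemotype`): eigen-decomposition of the covariance matrix
  of centered (optionally unit-scaled) data, with component signs fixed by
  making each loading's largest-magnitude entry positive. Centered,
  unscaled concentrations are the default because concentration PCA keeps
  dominant compounds dominant; `scale = TRUE` switches to correlation PCA.
  Published chemotype PCAs often do not state their scaling choice or
  whether they ran on concentrations or compositions, so reproducing any
  specific printed variance split requires a sweep over those choices —
  they are arguments here for exactly that reason. The implementation is
  tested against an SVD route (`prcomp`), keeping the eigen and SVD paths
  independent.

## 4. Carbocation cascade flux

Sesquiterpenes are grouped by the carbocation branchpoint their
biosynthesis proceeds through after FPP ionization: direct deprotonation of
the farnesyl cation (linear farnesenes), 1,11-ring closure to the humulyl
cation (humulenes, caryophyllenes), 1,10-closure to the
(*E,E*)-germacradienyl cation (germacrenes, selinenes, valencene and
relatives), or isomerization to NPP and the nerolidyl/bisabolyl branch.

The compound → class table is packaged data
(`inst/extdata/cascade_map.tsv`), not code: the assignments of γ-cadinene,
α-amorphene and camphene in particular are provisional (plausible
alternative routes exist), and an analyst who disagrees edits a TSV. Alias
resolution is case-insensitive and total; unknown compounds return
`"unassigned"` rather than erroring, and the unassigned class stays in the
flux denominator so that named-class percentages remain conservative and
the profile always sums to 100.

Replicates are averaged on the concentration scale *before* percentages are
formed (percentage-first averaging would weight low-emission replicates
equally with high ones). Uniform scaling of a sample's concentrations
leaves its flux profile unchanged, and moving one compound between classes
moves exactly its share.

## 5. Enzyme–product networks

Product-percentage profiles (one column per heterologously expressed
enzyme) become a directed bipartite network: enzyme → compound edges
weighted by the printed percentage, `major` iff weight > `major_threshold`
(default 10, strict). The strict inequality follows the operative
definition of a major volatile ("greater than 10%"); a figure caption
elsewhere describing thick edges as "<10%" is internally inconsistent with
that definition and is treated as a typo. Weights are used exactly as
printed — per-enzyme sums between 90 and 101 pass validation (printed
tables round each cell), and nothing is renormalized.

The packaged table keeps its two distinct rows labelled "β-Selinene" as
"β-Selinene (a)" and "β-Selinene (b)" — almost certainly a slip in the
original printing (one is plausibly another selinene isomer), but the
published values are preserved rather than silently merged; the alias
table maps both onto β-selinene for cascade assignment. Enzyme nodes take
the cascade class with the largest summed product percentage; ties break
lexicographically and are flagged. GraphML and edge-TSV exports round-trip
losslessly; SIF carries topology and edge class only.

## 6. ORF and motif screening

`find_longest_orf()` scans the three forward frames for ATG-initiated,
stop-terminated ORFs (cloned cDNA orientation is known; `both_strands =
TRUE` for raw input), returning the longest with ties broken by smallest
start. Codons containing `N` translate to `X`. `classify_cds()` calls an
isolate `premature_stop` when its protein is shorter than `min_fraction`
(default 0.9, inclusive boundary) of the reference protein — an
operational cutoff for "well short of full length", surfaced as an
argument, not a biological constant. `scan_tps_motifs()` reports all
(overlapping) matches of the canonical TPS motifs `RRx8W`, `DDxxD` and an
explicit simplification of the NSE/DTE consensus, `[ND]D[LIV]x[ST]xxxE`;
the patterns are arguments, since motif-scanner consensus definitions vary
between tools.

## 7. The synthetic-data generator

The generator exists so that every stage has a planted, *exact* ground
truth:

* `gen_probe_design()` plants probes into gene models at controlled
  mismatch counts and rejection-samples the background until no unplanted
  placement within the verification mismatch radius exists anywhere — the
  planted truth is then the complete map, not a lower bound. Ambiguous
  probes fill trailing genes first, so a design with `n_ambiguous = k ×
  probes_per_gene` has exactly `k` gene models covered only by ambiguous
  probes, making retained-gene counts derivable by construction (e.g. a
  49-model design with 14 ambiguous-only models retains 35).
* `gen_expression()` draws probe values around per-gene baselines on an
  RMA-like log2 scale and shifts a declared sample × gene block by
  `effect` standard deviations.
* `gen_volatile_study()` draws replicate concentrations as
  `mean × exp(N(0, σ))` — multiplicative lognormal noise, because
  concentrations are positive and right-skewed; σ = 0 reproduces the means
  exactly — and back-computes peak tables through the calibration curves
  so that `quantify()` is a round-trip identity at zero noise.

The default study design encodes the flower-chemotype structure the
pipeline is meant to resolve: 3 cultivars (MA, SB, SH) × 2 phenological
stages (EL-18 pre-anthesis, EL-26 full bloom) × 4 biological replicates ×
12 sesquiterpenes; one dominant compound per cultivar ((*E*)-β-farnesene,
(*E,E*)-α-farnesene, (+)-valencene respectively); MA means 74% higher for
(*E*)-β-farnesene at EL-18 than EL-26 and SH means 85% higher for
(*E,E*)-α-farnesene at EL-26 than EL-18; per-cell humulyl shares spanning
14.7–18.6% of total sesquiterpenes; and MA totals well below SB and SH.
Replicate noise defaults to σ = 0.15, a realistic ~15% CV for biological
replicates of headspace GC-MS.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: chromatographic reality (peak shapes, retention
drift, co-elution, integration error enter only as lognormal noise);
probe-level hybridization physics (mismatch position and GC content do not
modulate signal); correlated regulation between genes (background genes
are independent); RMA itself (matrices are consumed pre-normalized);
compositional correlation between compounds within a sample. Planted-truth
recovery demonstrates that the algorithms are correct, not that real
microarray or GC-MS noise is benign.

## 8. Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the full
suite completes in minutes on one core while remaining statistically
meaningful: 1,000 randomized probe/gene instances for the matching oracle,
100 random planted designs for classification recovery, a 49-model planted
remap, 100 seeded hotspot simulations on 20 genes × 24 samples (4 probes
per gene — the designed probe redundancy of the emulated platform — with
5 × 5 blocks at +3 sd), and 24 × 12 matrices for the PCA oracle. Floating
point tolerances: quantification round-trip and percentage sums at 1e-9;
PCA against the SVD oracle at 1e-8; negative eigenvalues from numerically
semidefinite covariance matrices clamp to zero before variance
percentages.

A note on the hotspot simulation design: with a single probe per gene and
a block spanning nearly half the samples, exact recovery of every block
member is information-theoretically marginal at +3 sd (the per-gene
evidence is a mean over five cells), and no detector of this family is
reliable there. The simulated conditions above — redundant probes, a
wider sample panel, a block occupying ~20% of samples — are the regime the
construct "hotspot in a tissue atlas" actually describes.

## 9. Known limitations

* The Hamming rule is a deterministic replacement for, not a reimplementation
  of, heuristic homology-search protocols; probe counts on real platforms
  can differ at the margin (strand handling, multi-placement collapse).
* Hotspot block boundaries on real atlas data are a heuristic call;
  recovery of any particular published hand-drawn block is not promised.
* The cascade map is a curated opinion table; contested assignments are
  data, flagged in comments.
* `validate_profiles()` accepts sums in [90, 101] by default and so will
  not flag a table whose rounding errors conspire within that window.
* Semi-quantitative concentrations inherit the fallback curve's slope; they
  are comparable within a compound across samples, but their absolute
  scale is only as good as the (+)-valencene surrogate assumption.
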