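---
title: "Methods: models, parameters and design choices in tfrewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in tfrewire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrewire)
```

# Scope

tfrewire implements the integrative analysis used to study how a set of
cooperating master transcription factors — MECOM, PAX8, SOX17 and WT1 —
redistribute their genomic binding sites and target genes between a benign
cellular context (fallopian tube secretory epithelium, FTSEC) and a
malignant one (high-grade serous ovarian cancer, HGSC). The package takes
peak calls, signal tracks, gene models, TAD calls and knockdown RNA-seq
count matrices as inputs; read alignment, peak calling and Hi-C matrix
processing are upstream of it and out of scope.

Because the interesting claims of such an analysis live in its integration
steps, the package ships a first-class synthetic-data module that plants
known structure — co-bound loci, hockey-stick enhancer landscapes, TADs,
knockdown effects, a signed regulatory circuit — and every downstream stage
is validated by recovering that planted truth.

# Super-enhancer calling

`stitch()` implements ROSE-style stitching: signal peaks within a stitch
distance are fused into regions, after excluding peaks that lie entirely
inside a TSS window so that promoter-proximal signal does not nucleate
enhancer regions. Defaults are the classic choices — stitch distance
12,500 bp, TSS exclusion ±2,500 bp — and both are arguments.

`call_super()` ranks stitched regions by total signal ascending, rescales
both the rank and the signal axis to [0, 1], and takes as cutpoint the
first rank position where the finite-difference slope of the curve exceeds
1 — the point at which a 45° tangent touches the hockey stick. Regions
above the cutpoint are super-enhancers. Consequences of this definition
that the tests pin down:

* an exactly linear curve has slope 1 everywhere, so it yields zero supers;
* min–max rescaling makes the call invariant to multiplying all signals by
  any positive constant;
* ties in the finite differences resolve toward the higher rank, i.e.
  toward fewer supers (the conservative direction);
* all-zero signal is degenerate: zero supers, with a warning.

The same stitch-plus-cutpoint procedure applied to H3K27me3 peak signal
defines "super-methylated" regions. That construction is an assumption —
the analysis tradition names the class without specifying its derivation —
and is recorded as such here; it is the natural analogue and is what
`build_state_map()` uses.

# Chromatin-state annotation

`build_state_map()` stores five classes — promoters (TSS ± 2,000 bp by
default), super- and typical enhancers from H3K27ac, super- and typical
methylated regions from H3K27me3 — without resolving overlaps between
classes. Overlaps are resolved only at annotation time:
`annotate_state()` assigns each query region exactly one label by the fixed
precedence promoter > super-enhancer > typical enhancer > super-methylated
> typical methylated > none, each judged by ≥ 1 bp overlap. The promoter
half-width is shared with target classification, which makes "on the
promoter" and "non-promoter" complementary by construction.

# Co-binding and context comparison

`count_cobinding()` merges all factors' peaks (gap 0) into union regions
and marks a factor bound wherever one of its peaks overlaps the region.
Both views of co-occupancy are reported — per union region (the count
bound by k = 0..4 factors) and per factor peak (the proportion of a
factor's peaks lying in regions bound by at least two factors) — because
the two denominators answer different questions and the analysis tradition
quotes both.

`compare_contexts()` calls a peak "common" when it overlaps any peak of
the other context, reports common regions as the gap-0 merge of all
reciprocally overlapping peaks (so shared binding is counted once, not
once per side), and defines
`fraction_common = common / (common + specific_A + specific_B)`.

# Permutation enrichment at enhancers

`enhancer_binding_permutation()` asks whether a set of enhancers is bound
by the factors more often than chance. The observed statistic is the
fraction of enhancers overlapping at least one peak of any factor. The
null relocates each enhancer uniformly at random within its own
chromosome, preserving its length; placements are independent and may
overlap each other. This conditions on the factor cistrome — the quantity
under test — rather than perturbing it. The empirical p-value is

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{N + 1},$$

which can never be zero; with the default N = 9,999 the smallest
attainable p is 10⁻⁴. The test is one-sided (enrichment) to match the
directional question. Two calibration facts matter in practice. First,
the statistic lives on a grid of 1/n_enhancers, so observed–null ties make
p conservatively super-uniform; with a few hundred enhancers the effect is
negligible, with a few dozen it is visible. Second, the null distribution
is computed exactly under the stated relocation model (starts drawn
uniformly on the feasible range), which the tests verify against exhaustive
placement enumeration on a tiny genome.

# Spike-in-anchored normalization

The expression module implements the global-shift-aware pipeline: TPM from
the count matrix (`tpm()`), then a cyclic pairwise normalization on
log2(TPM + 1) anchored on the exogenous spike-in rows
(`loess_normalize()`). For every sample pair, M (log-ratio) is smoothed
against A (log-mean) with a robust local-linear smoother
(`stats::lowess`, span 0.6) fitted on the anchor rows only and evaluated
on all rows (linear interpolation, constant extrapolation beyond the
anchor A-range). Each pass fits all pairs from the pass-start matrix and
then shifts each sample by the mean of its fitted pairwise offsets. We use
this accumulate-then-apply update rather than adjusting the matrix after
each pair inside the pass: sequential half-step updates feed each fit's
smoothing error into the next fit, which both slows convergence and makes
the accumulated error grow with the number of pairs, whereas the
accumulated update removes a constant per-sample offset exactly in one
pass and keeps smoother noise from compounding. Passes repeat until the
largest absolute median anchor M across pairs falls below 0.01, to at most
3 passes.

The anchoring logic is the scientific point: a shift that the spike-ins
exhibit too is technical and is removed; a shift confined to gene rows
while spike-ins are flat is certified as biological and preserved. This is
what lets the pipeline see genuine global transcriptional changes after a
knockdown that per-sample relative normalization would erase.
Normalization is applied within each cell line (`normalize_counts()`),
since every fold change is a within-line contrast and each line carries
its own spike-in measurements.

Fold changes (`log2fc()`) are the mean over knockdown replicates of
log2(TPM + 1) minus the mean over the pooled replicates of both control
conditions. Pooling (rather than averaging per-control means) is a
declared choice; with balanced replicates the two coincide. The
pseudocount of 1 on the TPM scale avoids −∞ and is configurable.

The "high-confidence" rule (`call_high_confidence()`) is deliberately the
effect-size rule that defines target genes in this analysis — absolute
log2FC ≥ 0.5 (inclusive) in **both** cell lines of a context with
concordant sign — not a dispersion-model test; no p-values or FDR
machinery are attached, and DESeq2-style shrinkage is intentionally not
re-implemented.

# TAD-aware target classification

`classify_targets()` integrates the three data types. For each
high-confidence DEG and factor: **direct** if a factor peak overlaps the
gene's promoter; else **putative** if the factor has any peak within the
TAD containing the gene's TSS; else **indirect**. Precedence makes the
three classes exclusive and exhaustive, which the tests assert as a
partition invariant. A gene whose TSS falls in no TAD can still be direct
through its promoter, otherwise it is indirect. Nested or overlapping
input domains are legal: the smallest domain containing the TSS scopes the
gene (the conservative choice). The evidence peaks supporting each call
are reported.

`build_circuit()` restricts the DEG table to the factor genes themselves
and draws a signed edge per high-confidence effect: a regulator
*activates* a target whose expression falls on the regulator's knockdown
and *represses* one that rises. Self-edges (autoregulation) are allowed.

# Tissue panel

`cluster_tissues()` k-means-clusters per-tissue mean profiles of the four
factors, z-scored per factor across tissues (20 restarts, best inertia,
seeded); hierarchical clustering (Ward.D2) is provided as an alternative
because both descriptions circulate for this kind of panel figure, and
neither mode claims to reproduce any particular published panel.
`rank_by_correlation()` ranks tissues by the mean Pearson correlation of
the six factor pairs across samples; undefined pairs (zero variance) are
dropped from the mean and flagged, ties break alphabetically and are
flagged. Expression is expected on a log scale (log2(TPM + 1) in the
simulated panel). `co_positivity()` applies the inclusive 0.1
positivity-rate threshold per factor and reports, per histotype, the
distribution of samples with 0–4 positive factors.

# The synthetic-data generator

`simulate_genome()`, `simulate_cistromes()`, `simulate_knockdown_counts()`
and `simulate_tissue_panel()` build a miniature study with machine-readable
planted truth. The geometry is laid out on a repeating 15 kb unit so that
stitching at the default 12,500 bp never fuses independently planted loci:
typical-enhancer units carry one H3K27ac peak and three gene TSSs;
super-enhancer loci occupy two consecutive units with four high-signal
constituents; H3K27me3 units carry 2 kb domains, with super-methylated
loci as three-domain pairs. All planted factor-binding loci are at least
100 bp apart, so a gap-0 union of the peak sets reproduces the planted
loci exactly, and the co-binding table can be compared to truth
region-by-region.

Signal levels are chosen so the hockey-stick cutpoint is deterministic:
typical regions draw signal uniformly on [1, 20] (bounded, dense — the
maximum order-statistic gap stays far below the slope-1 threshold), while
super-enhancer loci total 800–1,200, so the first slope crossing lands
exactly at the planted boundary and recovered super counts equal planted
counts.

Default conditions: 2 chromosomes × 1 Mb, 200 genes, 20 TADs, ~500
binding sites per factor per context, half of the loci context-specific,
92 spike-ins (the ERCC set size), planted knockdown effects of ±2 log2
units, log2-scale count noise of 0.1, and two control conditions per cell
line with four replicates per condition. Four replicates (rather than the
two technical duplicates typical of such experiments) is a power choice:
with noise 0.1 and duplicates, the sampling error of a per-line log2FC is
≈ 0.09, which no normalization can remove; four replicates bring the
context-level estimate (mean of the two lines) to ≈ 0.04, so the
pipeline's planted-effect recovery within ±0.1 is a property of the
method rather than of seed luck. Composition distortion is opt-in
(`global_shift`): gene rows of every knockdown sample are multiplied by
2^shift while spike-ins are drawn identically across samples, and the
planted truth records the total expected log2FC (effect + shift), which is
what a spike-in-anchored pipeline measures in absolute terms.

Planted targets are geometrically consistent by construction: direct
targets get a promoter-overlapping peak of the factor; putative targets
get a distal in-TAD peak and a scrubbed promoter neighbourhood; indirect
targets live in per-factor exclusion TADs the factor never binds. Planted
genes keep their whole ±2 kb promoter window inside their TAD so promoter
evidence cannot leak across a TAD boundary. When every locus is
context-specific (`fraction_context_specific = 1`), binding that must
cover both contexts is planted as two disjoint context-specific loci, so
the zero-common-peaks limit holds exactly.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level sampling (counts are log-normal, not
negative-binomial, because downstream uses only log-ratios and a
log-scale smoother), fragment-length and GC effects, irregular peak
shapes and widths, peaks straddling TAD boundaries, inter-gene correlation
structure, and batch effects beyond a single global composition shift.
Recovery rates on this idealized geometry are upper bounds on real-data
behaviour; the value of the tests is that they pin the *logic* of every
integration step, not its robustness to assay noise.

# Pipeline and reproducibility

`run_pipeline()` executes the stages in dependency order and writes every
stage's tables plus a manifest containing the package version, the seed,
the full parameterization and per-output checksums — and no timestamps —
so a rerun with the same config is byte-identical. All randomness flows
from explicit integer seeds through R's Mersenne-Twister generator
(inversion normals, rejection sampling), which the config echoes.

Problem sizes used by the test-suite and the acceptance script — the
default mini-genome above; 50 simulated datasets for noisy-label
recovery; 200 simulated datasets of 400 enhancers with 199 permutations
each for null calibration plus one 9,999-permutation planted run; fuzzed
oracle comparisons at up to 500 intervals — were chosen so the whole
suite completes in a few minutes on a single core while keeping every
statistical check well-powered.

# Known limitations

* The super-methylated construction is an analogy, not a published recipe.
* Gene–region assignment offers TAD scoping (with nearest-TSS fallback)
  and pure proximity; loop-based assignment is only a cross-check via
  `loop_anchor_overlap()`.
* The permutation null relocates enhancers within chromosomes uniformly;
  it does not preserve distance-to-gene or GC composition.
* The high-confidence rule is an effect-size filter; with very few
  replicates it has no error control beyond the two-line concordance
  requirement.
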