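# tfrewire

Master transcription factors (MTFs) are lineage-enriched,
super-enhancer-associated regulators whose cooperative binding defines
cell identity. In high-grade serous ovarian cancer (HGSC), the candidate
MTFs **MECOM, PAX8, SOX17 and WT1** are also expressed in the presumed
tissue of origin — fallopian tube secretory epithelial cells (FTSECs) —
yet the same four proteins bind largely different genomic sites and
regulate largely different genes in the two contexts. tfrewire is an R
package for quantifying that *cistrome rewiring* end to end, for analysts
working with CUT&RUN/CUT&TAG peak sets, H3K27ac/H3K27me3 landscapes, Hi-C
TAD calls and spike-in-controlled knockdown RNA-seq.

The package implements:

* **Super-enhancer calling** — ROSE-style stitching (default 12.5 kb, TSS
  exclusion ±2.5 kb) and the hockey-stick cutpoint: regions ranked by
  signal, both axes rescaled to [0, 1], supers are the regions above the
  first rank where the slope of the rank–signal curve exceeds 1.
* **Multi-TF co-occupancy** — union-region co-binding tables with
  chromatin-state annotation by fixed precedence (promoter >
  super-enhancer > typical enhancer > super-methylated > typical
  methylated > none).
* **Context comparison** — common vs context-specific binding sites per
  factor, with merged counting of shared regions.
* **Permutation enrichment** — is a set of enhancers bound by the factors
  more than chance? Length-preserving uniform relocation within
  chromosomes; `p = (1 + #{null ≥ obs}) / (N + 1)`, minimum 10⁻⁴ at the
  default N = 9,999.
* **Spike-in-anchored normalization** — TPM followed by cyclic pairwise
  local-linear (loess-type) normalization fitted on ERCC spike-in rows
  only, so global transcriptional shifts that spike-ins certify as
  biological are *preserved* while spike-in-tracked technical distortion
  is removed; then the high-confidence rule: |log2FC| ≥ 0.5 in **both**
  cell lines of a context with concordant sign.
* **TAD-aware target classification** — every high-confidence DEG is a
  **direct** (factor peak on the gene promoter), **putative** (factor
  peak elsewhere in the gene's TAD) or **indirect** (no factor peak in
  the TAD) target, with precedence in that order.
* **Core-regulatory-circuit inference** — signed regulator→target edges
  among the four factors from their mutual knockdown responses.
* **Tissue panel analyses** — k-means clustering of tissues on 4-TF
  expression, ranking by mean pairwise Pearson correlation, and IHC
  co-positivity at the 0.1 threshold.
* **A synthetic-data generator** with planted ground truth (co-bound
  loci, hockey-stick landscapes, TADs, knockdown effects, a planted
  circuit), making the whole pipeline testable without any downloads.

Everything is tibble-in/tibble-out and pipe-friendly; result objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate the default miniature study (2 × 1 Mb genome, 200 genes, 20
TADs, ~500 peaks per factor per context, 92 spike-ins) and run the main
stages:

```r
library(tfrewire)

cfg <- sim_config(seed = 7, noise_sd = 0)
gp  <- simulate_genome(cfg)
cis <- simulate_cistromes(cfg, gp)

# super-enhancers in the tumor context
sc <- peaks_for(cis$h3k27ac, "HGSC") |>
  stitch(genes = gp$genes) |>
  call_super()
sc
#> Super-enhancer call: 9 super / 73 stitched regions
#> cutpoint signal: 19.83
glance(sc)
#> # A tibble: 1 × 4
#>   n_regions n_super cutpoint_signal super_signal_fraction
#>       <int>   <int>           <dbl>                 <dbl>
#> 1        73       9            19.8                 0.937
```

Nine stitched regions carry 94% of the acetylation signal — the planted
super-enhancers, recovered exactly. Next, knockdown expression and target
classification:

```r
kd  <- simulate_knockdown_counts(cfg, gp, cis$truth)
deg <- kd$counts |>
  normalize_counts(kd$samples) |>       # TPM + spike-in-anchored loess
  log2fc_table(kd$samples) |>
  call_high_confidence()                # |log2FC| >= 0.5 in both lines
sum(deg$high_confidence)
#> [1] 139

classify_targets(deg, cis$tf_peaks[cis$tf_peaks$context == "HGSC", ],
                 gp$genes, gp$tads, context = "HGSC") |>
  dplyr::count(tf, mode)
#> # A tibble: 12 × 3
#>    tf    mode         n
#>  1 MECOM direct       8
#>  2 MECOM indirect     4
#>  3 MECOM putative     5
#>  ...
```

Each factor's high-confidence DEGs partition into direct, putative and
indirect targets; at zero noise the labels match the planted truth
gene-for-gene. Finally, the circuit among the factors themselves:

```r
glance(build_circuit(deg))
#> # A tibble: 1 × 4
#>   n_edges n_activating n_repressing n_autoregulatory
#> 1      27           24            3                8
```

`run_pipeline(pipeline_config(seed = 7), outdir = "out")` executes all
stages on one command and writes every table plus a timestamp-free
manifest; reruns are byte-identical.

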