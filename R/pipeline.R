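# One-command orchestration of the full analysis on simulated or supplied
# inputs, with a deterministic run manifest.

#' Simulate chromatin loops anchored at super-enhancer constituents
#'
#' Emits a BEDPE-style loop table: one loop per planted super-enhancer
#' locus (anchored at its first constituent) plus background loops at
#' random positions.
#'
#' @param config A [sim_config()].
#' @param truth `tfrewire_truth` from [simulate_cistromes()].
#' @param n_background Number of unanchored background loops.
#' @return Loop tibble (`chrom1`, `start1`, `end1`, `chrom2`, `start2`,
#'   `end2`).
#' @export
simulate_loops <- function(config, truth, n_background = 20) {
  set_sim_seed(config$seed + 4L)
  se <- dplyr::distinct(truth$superenhancers, .data$chrom, .data$start,
                        .data$end)
  anchored <- tibble::tibble(
    chrom1 = se$chrom, start1 = se$start + 100, end1 = se$start + 900,
    chrom2 = se$chrom,
    start2 = pmin(se$end + 50000, config$chrom_length - 2000),
    end2 = pmin(se$end + 51000, config$chrom_length - 1000))
  bg_chrom <- paste0("chr", sample(config$n_chroms, n_background, replace = TRUE))
  bg_start <- floor(stats::runif(n_background, 0, config$chrom_length - 120000))
  background <- tibble::tibble(
    chrom1 = bg_chrom, start1 = bg_start, end1 = bg_start + 1000,
    chrom2 = bg_chrom, start2 = bg_start + 100000, end2 = bg_start + 101000)
  dplyr::bind_rows(anchored, background)
}

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults matching the individual
#' functions; the config is serialized verbatim into the run manifest.
#'
#' @param seed Master seed (also seeds the simulator unless `sim` given).
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param stitch_distance,tss_window,promoter_window Enhancer parameters, bp.
#' @param threshold High-confidence log2FC threshold.
#' @param span,pseudocount,anchor Normalization parameters.
#' @param n_permutations Enhancer permutation count.
#' @param profile_window,profile_bin Signal-matrix geometry, bp.
#' @param k_clusters Tissue-panel cluster count.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 7, sim = NULL, stitch_distance = 12500,
                            tss_window = 2500, promoter_window = 2000,
                            threshold = 0.5, span = 0.6, pseudocount = 1,
                            anchor = "spikeins_only", n_permutations = 9999,
                            profile_window = 3000, profile_bin = 100,
                            k_clusters = 5) {
  structure(list(seed = as.integer(seed),
                 sim = if (is.null(sim)) sim_config(seed = seed) else sim,
                 stitch_distance = stitch_distance, tss_window = tss_window,
                 promoter_window = promoter_window, threshold = threshold,
                 span = span, pseudocount = pseudocount, anchor = anchor,
                 n_permutations = as.integer(n_permutations),
                 profile_window = profile_window, profile_bin = profile_bin,
                 k_clusters = as.integer(k_clusters)),
            class = "pipeline_config")
}

write_stage <- function(x, outdir, name) {
  path <- file.path(outdir, name)
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run the full analysis end to end
#'
#' Executes the stages in dependency order — simulate (or load inputs),
#' enhancer landscape, co-binding and context comparison, permutation
#' enrichment, signal profiles, spike-in normalized differential
#' expression, target classification and circuit inference, tissue panel —
#' writing each stage's tables under `outdir` together with a run manifest
#' (parameters, seeds, per-stage row counts and output checksums; no
#' timestamps, so reruns of deterministic stages are byte-identical).
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param simulate Generate inputs with the synthetic-data module
#'   (default). With `simulate = FALSE`, `inputs` must supply file paths.
#' @param inputs Named list of paths used when `simulate = FALSE`:
#'   `genes`, `tads`, `counts`, `samples`, plus per-context named lists
#'   `tf_peaks` and `h3k27ac` (and optionally `h3k27me3`, `expression`,
#'   `positivity`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         simulate = TRUE, inputs = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "tfrewire",
                   version = as.character(utils::packageVersion("tfrewire")),
                   seed = config$seed, config = unclass(config),
                   stages = list())
  manifest$config$sim <- unclass(manifest$config$sim)

  ## ---- stage: inputs ------------------------------------------------------
  if (simulate) {
    gp <- simulate_genome(config$sim)
    cis <- simulate_cistromes(config$sim, gp)
    kd <- simulate_knockdown_counts(config$sim, gp, cis$truth)
    panel <- simulate_tissue_panel(config$sim)
    loops <- simulate_loops(config$sim, cis$truth)
    write_stage(gp$genes, outdir, "genes.tsv")
    write_stage(gp$tads[, c("chrom", "start", "end", "tad_id")], outdir, "tads.tsv")
    write_stage(cis$tf_peaks, outdir, "tf_peaks.tsv")
    write_stage(cis$h3k27ac, outdir, "h3k27ac_peaks.tsv")
    write_stage(cis$h3k27me3, outdir, "h3k27me3_peaks.tsv")
    write_stage(kd$counts, outdir, "counts.tsv")
    write_stage(kd$samples, outdir, "samples.tsv")
    write_stage(loops, outdir, "loops.bedpe")
    write_stage(panel$expression, outdir, "tissue_expression.tsv")
    write_stage(panel$positivity, outdir, "ihc_positivity.tsv")
    write_truth(kd$truth, file.path(outdir, "truth.json"))
    genome <- gp$genome
    genes <- gp$genes
    tads <- gp$tads
    tf_peaks <- cis$tf_peaks
    h3k27ac <- cis$h3k27ac
    h3k27me3 <- cis$h3k27me3
    counts <- kd$counts
    samples <- kd$samples
    expression <- panel$expression
    positivity <- panel$positivity
    manifest$stages$simulate <- list(
      n_genes = nrow(genes), n_tads = nrow(tads),
      n_tf_peaks = nrow(tf_peaks), n_loops = nrow(loops))
  } else {
    need <- c(genes = "genome_intervals", tads = "target_wiring",
              counts = "expression_deg", samples = "expression_deg",
              tf_peaks = "cistrome_cobinding", h3k27ac = "enhancer_landscape")
    for (nm in names(need)) {
      if (is.null(inputs[[nm]])) {
        stop(sprintf("stage %s: missing required input '%s'", need[[nm]], nm))
      }
    }
    genes <- readr::read_tsv(inputs$genes, show_col_types = FALSE)
    tads <- readr::read_tsv(inputs$tads, show_col_types = FALSE)
    if (!"tad_id" %in% names(tads)) {
      tads$tad_id <- sprintf("tad_%02d", seq_len(nrow(tads)))
    }
    tf_peaks <- readr::read_tsv(inputs$tf_peaks, show_col_types = FALSE)
    h3k27ac <- readr::read_tsv(inputs$h3k27ac, show_col_types = FALSE)
    h3k27me3 <- if (!is.null(inputs$h3k27me3)) {
      readr::read_tsv(inputs$h3k27me3, show_col_types = FALSE)
    } else NULL
    counts <- readr::read_tsv(inputs$counts, show_col_types = FALSE)
    samples <- readr::read_tsv(inputs$samples, show_col_types = FALSE)
    expression <- if (!is.null(inputs$expression)) {
      readr::read_tsv(inputs$expression, show_col_types = FALSE)
    } else NULL
    positivity <- if (!is.null(inputs$positivity)) {
      readr::read_tsv(inputs$positivity, show_col_types = FALSE)
    } else NULL
    loops <- if (!is.null(inputs$loops)) read_bedpe(inputs$loops) else NULL
    genome <- genes |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(length = max(.data$tss) + 1e6, .groups = "drop")
    manifest$stages$load <- list(n_genes = nrow(genes), n_tads = nrow(tads))
  }
  contexts <- sort(unique(tf_peaks$context))
  tf_names <- sort(unique(tf_peaks$tf))

  ## ---- stage: enhancer landscape ------------------------------------------
  state_maps <- list()
  enh_regions <- list()
  for (ctx in contexts) {
    ac <- peaks_for(h3k27ac, ctx)
    me <- if (!is.null(h3k27me3) && nrow(h3k27me3) > 0) {
      peaks_for(h3k27me3, ctx)
    } else NULL
    reg <- stitch(ac, stitch_distance = config$stitch_distance,
                  genes = genes, tss_window = config$tss_window)
    sc <- call_super(reg)
    enh_regions[[ctx]] <- sc
    state_maps[[ctx]] <- build_state_map(
      ac, me, genes, promoter_window = config$promoter_window,
      stitch_distance = config$stitch_distance,
      tss_window = config$tss_window, context = ctx)
    write_stage(tidy(sc) |> dplyr::mutate(context = ctx), outdir,
                paste0("enhancers_", ctx, ".tsv"))
  }
  if (!is.null(loops)) {
    anchoring <- purrr::map_dfr(contexts, function(ctx) {
      la <- loop_anchor_overlap(loops, enh_regions[[ctx]]$regions)
      tibble::tibble(context = ctx,
                     fraction_super_anchored = la$fraction_super_anchored)
    })
    write_stage(anchoring, outdir, "loop_anchoring.tsv")
  }
  manifest$stages$enhancers <- lapply(enh_regions, function(sc) {
    list(n_regions = sc$n_regions, n_super = sc$n_super)
  })

  ## ---- stage: co-binding and context comparison ---------------------------
  cob <- list()
  for (ctx in contexts) {
    sets <- lapply(stats::setNames(tf_names, tf_names), function(tf) {
      peaks_for(tf_peaks, ctx, tf)
    })
    cob[[ctx]] <- count_cobinding(sets, state_maps[[ctx]])
    write_stage(tidy(cob[[ctx]]) |> dplyr::mutate(context = ctx), outdir,
                paste0("cobinding_", ctx, ".tsv"))
    write_stage(cob[[ctx]]$per_tf |> dplyr::mutate(context = ctx), outdir,
                paste0("cobinding_per_tf_", ctx, ".tsv"))
  }
  comparison <- NULL
  if (length(contexts) == 2) {
    comparison <- purrr::map_dfr(tf_names, function(tf) {
      cc <- compare_contexts(peaks_for(tf_peaks, contexts[1], tf),
                             peaks_for(tf_peaks, contexts[2], tf),
                             labels = contexts)
      dplyr::mutate(cc$summary, tf = tf, .before = 1)
    })
    write_stage(comparison, outdir, "context_comparison.tsv")
  }
  manifest$stages$cobinding <- lapply(cob, function(x) {
    list(n_regions = nrow(x$regions))
  })

  ## ---- stage: permutation enrichment at context-specific enhancers --------
  perms <- list()
  if (length(contexts) == 2) {
    for (ctx in contexts) {
      other <- setdiff(contexts, ctx)
      mine <- enh_regions[[ctx]]$regions[, c("chrom", "start", "end")]
      theirs <- enh_regions[[other]]$regions[, c("chrom", "start", "end")]
      specific <- mine[!overlaps_any(mine, theirs), ]
      if (nrow(specific) == 0) next
      sets <- lapply(stats::setNames(tf_names, tf_names), function(tf) {
        peaks_for(tf_peaks, ctx, tf)
      })
      pt <- enhancer_binding_permutation(
        specific, sets, genome, n_permutations = config$n_permutations,
        seed = config$seed + match(ctx, contexts))
      perms[[ctx]] <- pt
      write_stage(tidy(pt) |> dplyr::mutate(context = ctx), outdir,
                  paste0("enhancer_binding_k_", ctx, ".tsv"))
    }
    perm_summary <- purrr::imap_dfr(perms, function(pt, ctx) {
      dplyr::mutate(glance(pt), context = ctx, .before = 1)
    })
    if (nrow(perm_summary)) {
      write_stage(perm_summary, outdir, "permutation_summary.tsv")
    }
  }
  manifest$stages$permutation <- lapply(perms, function(pt) {
    list(observed = pt$observed, p_value = pt$p_value)
  })

  ## ---- stage: signal profiles ---------------------------------------------
  if (length(contexts) == 2 && "PAX8" %in% tf_names) {
    ctx <- contexts[1]
    track <- h3k27ac |>
      dplyr::filter(.data$context == ctx) |>
      dplyr::transmute(chrom = .data$chrom, start = .data$start,
                       end = .data$end, value = .data$signal) |>
      as_intervals()
    cc <- compare_contexts(peaks_for(tf_peaks, contexts[1], "PAX8"),
                           peaks_for(tf_peaks, contexts[2], "PAX8"),
                           labels = contexts)
    centers <- cc$peaks |>
      dplyr::filter(.data$class == "specific_a") |>
      dplyr::select("chrom", "start", "end")
    if (nrow(centers) > 0) {
      sm <- signal_matrix(track, centers, window = config$profile_window,
                          bin = config$profile_bin, library_size = 1e6,
                          genome = genome)
      utils::write.table(round(sm, 6), file.path(outdir, "profile_matrix.tsv"),
                         sep = "\t", quote = FALSE, col.names = FALSE,
                         row.names = FALSE)
      manifest$stages$profile <- list(n_rows = nrow(sm), n_bins = ncol(sm))
    }
  }

  ## ---- stage: differential expression -------------------------------------
  norm <- normalize_counts(counts, samples, anchor = config$anchor,
                           span = config$span,
                           pseudocount = config$pseudocount)
  lfc <- log2fc_table(norm, samples, pseudocount = config$pseudocount)
  deg <- call_high_confidence(lfc, threshold = config$threshold)
  write_stage(deg, outdir, "deg_table.tsv")
  manifest$stages$deg <- list(
    n_tested = nrow(deg), n_high_confidence = sum(deg$high_confidence))

  ## ---- stage: targets and circuit -----------------------------------------
  calls <- purrr::map(stats::setNames(contexts, contexts), function(ctx) {
    classify_targets(deg, tf_peaks[tf_peaks$context == ctx, ], genes, tads,
                     context = ctx, promoter_window = config$promoter_window)
  })
  for (ctx in contexts) {
    write_stage(calls[[ctx]], outdir, paste0("target_calls_", ctx, ".tsv"))
  }
  if (length(contexts) == 2) {
    rw <- rewiring_summary(calls[[1]], calls[[2]])
    write_stage(rw$per_tf, outdir, "rewiring_per_tf.tsv")
    write_stage(rw$transitions, outdir, "rewiring_transitions.tsv")
  }
  circuit <- build_circuit(deg)
  write_stage(tidy(circuit), outdir, "circuit_edges.tsv")
  write_circuit_dot(circuit, file.path(outdir, "circuit.dot"))
  manifest$stages$targets <- lapply(calls, function(x) {
    as.list(table(x$mode))
  })
  manifest$stages$circuit <- list(n_edges = nrow(circuit$edges))

  ## ---- stage: tissue panel ------------------------------------------------
  if (!is.null(expression)) {
    cl <- cluster_tissues(expression, k = config$k_clusters,
                          seed = config$seed)
    rk <- rank_by_correlation(expression)
    write_stage(tidy(cl), outdir, "tissue_clusters.tsv")
    write_stage(rk, outdir, "tissue_correlation_rank.tsv")
    manifest$stages$panel <- list(k = config$k_clusters,
                                  top_tissue = rk$tissue[1])
  }
  if (!is.null(positivity)) {
    cp <- co_positivity(positivity)
    write_stage(cp$per_histotype, outdir, "co_positivity.tsv")
    manifest$stages$panel$co_stain <- stats::setNames(
      as.list(cp$co_stain_all4$co_stain_all4), cp$co_stain_all4$histotype)
  }

  ## ---- manifest -----------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir), "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, outputs))
  manifest$outputs <- stats::setNames(as.list(unname(sums)), outputs)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
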