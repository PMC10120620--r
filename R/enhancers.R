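# ROSE-style enhancer stitching and hockey-stick super-enhancer calling.

#' Stitch signal peaks into enhancer regions
#'
#' Peaks within `stitch_distance` of one another are fused into regions
#' whose signal is the sum of their constituents (classic ROSE stitching).
#' When gene models are supplied, peaks falling entirely inside a TSS
#' exclusion window are removed before stitching, so promoter-proximal
#' acetylation does not nucleate enhancer regions.
#'
#' @param peaks Interval tibble with a `signal` column.
#' @param stitch_distance Maximum gap fused across, bp (default 12,500).
#' @param genes Optional gene-model tibble (`gene_id`, `chrom`, `tss`).
#' @param tss_window Half-width of the TSS exclusion window, bp.
#' @return A tibble of stitched regions (`region_id`, `chrom`, `start`,
#'   `end`, `n_constituents`, `total_signal`) with a `constituents`
#'   list-column of member-peak tibbles.
#' @export
stitch <- function(peaks, stitch_distance = 12500, genes = NULL,
                   tss_window = 2500) {
  if (stitch_distance < 0) stop("stitch_distance must be >= 0")
  peaks <- as_intervals(peaks)
  if (!"signal" %in% names(peaks)) stop("peaks must carry a signal column")
  if (!is.null(genes) && nrow(peaks) > 0) {
    tsswin <- tibble::tibble(chrom = genes$chrom,
                             start = pmax(genes$tss - tss_window, 0),
                             end = genes$tss + tss_window)
    gr_p <- iv_to_gr(peaks)
    gr_w <- iv_to_gr(as_intervals(tsswin))
    hits <- GenomicRanges::findOverlaps(gr_p, gr_w, type = "within")
    drop <- unique(S4Vectors::queryHits(hits))
    if (length(drop)) peaks <- peaks[-drop, ]
  }
  if (nrow(peaks) == 0) {
    return(tibble::tibble(region_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_constituents = integer(), total_signal = numeric(),
                          constituents = list()))
  }
  gr <- iv_to_gr(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1,
                               with.revmap = TRUE)
  out <- gr_to_iv(red)
  revmap <- S4Vectors::mcols(red)$revmap
  out$region_id <- sprintf("region_%04d", seq_len(nrow(out)))
  out$n_constituents <- lengths(revmap)
  out$total_signal <- vapply(revmap, function(i) sum(peaks$signal[i]), numeric(1))
  out$constituents <- lapply(revmap, function(i) peaks[i, ])
  out[, c("region_id", "chrom", "start", "end", "n_constituents",
          "total_signal", "constituents")]
}

#' Call super-enhancers with the hockey-stick cutpoint
#'
#' Regions are ranked by total signal ascending and both axes rescaled to
#' `[0, 1]`. The cutpoint is the first rank position at which the slope of
#' the rank-versus-signal curve exceeds 1 — the point where a 45-degree
#' tangent touches the hockey stick. Regions above the cutpoint are flagged
#' super. An exactly linear curve has slope 1 everywhere and yields zero
#' supers, as do all-zero signals (with a warning). Finite-difference ties
#' resolve toward the higher rank, i.e. fewer supers.
#'
#' @param regions Stitched-region tibble from [stitch()] (needs
#'   `total_signal`), or any tibble with a `total_signal` column.
#' @return An `se_call` object: `$regions` with `rank` (1 = highest signal)
#'   and `is_super` added, plus cutpoint metadata. Scale-invariant:
#'   multiplying all signals by a positive constant leaves flags unchanged.
#' @export
call_super <- function(regions) {
  stopifnot(is.data.frame(regions), "total_signal" %in% names(regions))
  n <- nrow(regions)
  if (n < 2) stop("need at least 2 regions to call supers")
  sig <- regions$total_signal
  if (any(sig < 0)) stop("signals must be nonnegative")
  ord <- order(sig)                       # ascending
  s <- sig[ord]
  is_super_sorted <- rep(FALSE, n)
  cut_rank <- NA_integer_
  if (max(s) == min(s)) {
    if (max(s) == 0) warning("all-zero signals: no super-enhancers called")
    # flat curve: degenerate, zero supers
  } else {
    x <- (seq_len(n) - 1) / (n - 1)
    y <- (s - s[1]) / (s[n] - s[1])
    slope <- diff(y) / diff(x)            # slope between rank i and i+1
    first <- which(slope > 1)[1]
    if (!is.na(first)) {
      cut_rank <- first                    # positions first+1 .. n are super
      is_super_sorted[(first + 1):n] <- TRUE
    }
  }
  out <- regions
  out$rank <- n + 1 - rank(sig, ties.method = "first")  # 1 = highest signal
  is_super <- logical(n)
  is_super[ord] <- is_super_sorted
  out$is_super <- is_super
  structure(list(
    regions = tibble::as_tibble(out),
    n_regions = n,
    n_super = sum(is_super),
    cutpoint_signal = if (!is.na(cut_rank)) s[cut_rank] else NA_real_
  ), class = "se_call")
}

#' @export
print.se_call <- function(x, ...) {
  cat("Super-enhancer call: ", x$n_super, " super / ", x$n_regions,
      " stitched regions\n", sep = "")
  if (!is.na(x$cutpoint_signal)) {
    cat("cutpoint signal:", format(x$cutpoint_signal, digits = 4), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a super-enhancer call into one row per region
#' @param x An `se_call` object.
#' @param ... Unused.
#' @export
tidy.se_call <- function(x, ...) {
  dplyr::select(x$regions, -dplyr::any_of("constituents"))
}

#' One-row summary of a super-enhancer call
#' @param x An `se_call` object.
#' @param ... Unused.
#' @export
glance.se_call <- function(x, ...) {
  tibble::tibble(n_regions = x$n_regions, n_super = x$n_super,
                 cutpoint_signal = x$cutpoint_signal,
                 super_signal_fraction =
                   sum(x$regions$total_signal[x$regions$is_super]) /
                   sum(x$regions$total_signal))
}

#' Hockey-stick plot of a super-enhancer call
#' @param object An `se_call` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.se_call <- function(object, ...) {
  df <- object$regions
  df$rank_asc <- object$n_regions + 1 - df$rank
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_asc, y = .data$total_signal,
                                   colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "regions ranked by signal", y = "total signal",
                  colour = "super-enhancer") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Build a chromatin-state map for one cellular context
#'
#' Promoters are TSS +/- `promoter_window`. H3K27ac peaks are stitched and
#' supers called, splitting enhancer regions into super and typical; the
#' identical procedure on H3K27me3 yields super- and typical-methylated
#' regions. Classes are stored unmodified; overlaps between classes are
#' resolved only when a query region is annotated (see [annotate_state()]).
#'
#' @param h3k27ac,h3k27me3 Signal-peak interval tibbles (H3K27me3 may be
#'   empty, giving empty methylated classes).
#' @param genes Gene models (`gene_id`, `chrom`, `tss`).
#' @param promoter_window Promoter half-width, bp (default 2,000).
#' @param stitch_distance,tss_window Passed to [stitch()].
#' @param context Label stored on the map.
#' @return A `chromatin_state_map`: list of five merged interval tibbles
#'   (`promoters`, `super_enhancers`, `typical_enhancers`,
#'   `super_methylated`, `typical_methylated`) plus `context`.
#' @export
build_state_map <- function(h3k27ac, h3k27me3 = NULL, genes,
                            promoter_window = 2000, stitch_distance = 12500,
                            tss_window = 2500, context = "context") {
  if (is.null(genes) || nrow(genes) == 0) stop("gene models are required")
  promoters <- merge_intervals(
    tibble::tibble(chrom = genes$chrom,
                   start = pmax(genes$tss - promoter_window, 0),
                   end = genes$tss + promoter_window))
  split_classes <- function(peaks) {
    empty <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric())
    if (is.null(peaks) || nrow(peaks) == 0) {
      return(list(super = empty, typical = empty))
    }
    reg <- stitch(peaks, stitch_distance = stitch_distance, genes = genes,
                  tss_window = tss_window)
    if (nrow(reg) < 2) {
      return(list(super = empty,
                  typical = as_intervals(reg[, c("chrom", "start", "end")])))
    }
    sc <- call_super(reg)
    list(super = as_intervals(sc$regions[sc$regions$is_super,
                                         c("chrom", "start", "end")]),
         typical = as_intervals(sc$regions[!sc$regions$is_super,
                                           c("chrom", "start", "end")]))
  }
  ac <- split_classes(h3k27ac)
  me <- split_classes(h3k27me3)
  structure(list(promoters = promoters[, c("chrom", "start", "end")],
                 super_enhancers = ac$super,
                 typical_enhancers = ac$typical,
                 super_methylated = me$super,
                 typical_methylated = me$typical,
                 context = context),
            class = "chromatin_state_map")
}

#' @export
print.chromatin_state_map <- function(x, ...) {
  cat("Chromatin state map [", x$context, "]\n", sep = "")
  for (nm in c("promoters", "super_enhancers", "typical_enhancers",
               "super_methylated", "typical_methylated")) {
    cat(sprintf("  %-20s %d regions\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Assign regions to genes, scoped by TADs
#'
#' In `"tad"` mode a region is assigned to every gene whose TSS lies in the
#' TAD containing the region's midpoint; regions outside any TAD (or in a
#' TAD with no genes) fall back to the nearest TSS on the same chromosome.
#' `"nearest"` mode assigns every region to its nearest TSS directly.
#'
#' @param regions Interval tibble (e.g. stitched enhancer regions).
#' @param genes Gene models with `gene_id`, `chrom`, `tss`.
#' @param tads TAD tibble (`chrom`, `start`, `end`); required in tad mode.
#' @param mode `"tad"` (default) or `"nearest"`.
#' @return A tibble pairing region rows (`region_idx`, coordinates) with
#'   `gene_id`, plus the assignment `basis` (`"tad"` or `"nearest"`).
#' @export
assign_regions_to_genes <- function(regions, genes, tads = NULL,
                                    mode = c("tad", "nearest")) {
  mode <- match.arg(mode)
  regions <- as_intervals(regions)
  if (nrow(regions) == 0) {
    return(tibble::tibble(region_idx = integer(), chrom = character(),
                          start = numeric(), end = numeric(),
                          gene_id = character(), basis = character()))
  }
  mid <- (regions$start + regions$end) %/% 2
  nearest_gene <- function(chrom, pos) {
    g <- genes[genes$chrom == chrom, ]
    if (nrow(g) == 0) return(NA_character_)
    g$gene_id[which.min(abs(g$tss - pos))]
  }
  rows <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    base <- tibble::tibble(region_idx = i, chrom = regions$chrom[i],
                           start = regions$start[i], end = regions$end[i])
    if (mode == "tad" && !is.null(tads)) {
      tid <- locate_tad(regions$chrom[i], mid[i], tads)
      if (!is.na(tid)) {
        tad <- tads[tads$tad_id == tid, ]
        hit <- genes[genes$chrom == tad$chrom & genes$tss >= tad$start &
                       genes$tss < tad$end, ]
        if (nrow(hit) > 0) {
          return(dplyr::mutate(tidyr::crossing(base, gene_id = hit$gene_id),
                               basis = "tad"))
        }
      }
    }
    dplyr::mutate(base, gene_id = nearest_gene(regions$chrom[i], mid[i]),
                  basis = "nearest")
  })
  rows[!is.na(rows$gene_id), ]
}

#' Overlap of chromatin-loop anchors with constituent enhancers
#'
#' A loop is anchored at a stitched region when either of its anchors,
#' padded by `slop`, overlaps one of the region's constituent peaks.
#'
#' @param loops BEDPE tibble from [read_bedpe()].
#' @param regions Stitched-region tibble from [stitch()] (needs the
#'   `constituents` list-column), optionally after [call_super()] via
#'   `tidy()`-free access to `$regions`.
#' @param slop Padding added to each anchor, bp.
#' @return A list: `per_region` (region_id, n_loops) and
#'   `fraction_super_anchored` — the fraction of super-flagged regions (all
#'   regions when no `is_super` column is present) with at least one
#'   anchored loop.
#' @export
loop_anchor_overlap <- function(loops, regions, slop = 0) {
  stopifnot(is.data.frame(loops), is.data.frame(regions))
  if (slop < 0) stop("slop must be >= 0")
  per_region <- tibble::tibble(region_id = regions$region_id, n_loops = 0L)
  if (nrow(loops) > 0 && nrow(regions) > 0) {
    anchors <- dplyr::bind_rows(
      tibble::tibble(loop = seq_len(nrow(loops)), chrom = loops$chrom1,
                     start = pmax(loops$start1 - slop, 0),
                     end = loops$end1 + slop),
      tibble::tibble(loop = seq_len(nrow(loops)), chrom = loops$chrom2,
                     start = pmax(loops$start2 - slop, 0),
                     end = loops$end2 + slop))
    cons <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
      dplyr::mutate(regions$constituents[[i]][, c("chrom", "start", "end")],
                    region_id = regions$region_id[i])
    })
    # overlap_pairs indexes into sorted inputs; sort here so the indices map
    anchors <- as_intervals(anchors)
    cons <- as_intervals(cons)
    ov <- overlap_pairs(anchors, cons)
    if (nrow(ov) > 0) {
      hit <- tibble::tibble(loop = anchors$loop[ov$idx_a],
                            region_id = cons$region_id[ov$idx_b]) |>
        dplyr::distinct() |>
        dplyr::count(.data$region_id, name = "n_loops")
      per_region <- per_region |>
        dplyr::rows_update(hit, by = "region_id")
    }
  }
  sel <- if ("is_super" %in% names(regions)) regions$is_super else
    rep(TRUE, nrow(regions))
  frac <- if (any(sel)) {
    mean(per_region$n_loops[match(regions$region_id[sel],
                                  per_region$region_id)] > 0)
  } else 0
  list(per_region = per_region, fraction_super_anchored = frac)
}
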