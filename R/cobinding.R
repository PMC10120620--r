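# Multi-TF co-occupancy, chromatin-state annotation, context comparison,
# permutation enrichment at enhancers, and signal-profile matrices.

#' Annotate regions with a chromatin state
#'
#' Each region receives exactly one label by fixed precedence
#' promoter > super_enhancer > typical_enhancer > super_methylated >
#' typical_methylated > none, where membership in a class means >= 1 bp
#' overlap with any region of that class.
#'
#' @param regions Interval tibble.
#' @param state_map A `chromatin_state_map` from [build_state_map()].
#' @return Character vector of state labels, one per input row (in the
#'   sorted order `as_intervals()` imposes).
#' @export
annotate_state <- function(regions, state_map) {
  stopifnot(inherits(state_map, "chromatin_state_map"))
  regions <- as_intervals(regions)
  n <- nrow(regions)
  out <- rep("none", n)
  classes <- c("typical_methylated", "super_methylated", "typical_enhancers",
               "super_enhancers", "promoters")
  labels <- c("typical_methylated", "super_methylated", "typical_enhancer",
              "super_enhancer", "promoter")
  for (i in seq_along(classes)) {   # ascending precedence; later overwrite
    hit <- overlaps_any(regions, state_map[[classes[i]]])
    out[hit] <- labels[i]
  }
  out
}

#' Count multi-factor co-binding over union regions
#'
#' Union regions are the gap-0 merge of all peaks across the supplied
#' factors; a factor is bound at a region when at least one of its peaks
#' overlaps it. Each region is annotated with exactly one chromatin state.
#' Also reports, per factor, the proportion of its peaks lying in regions
#' co-bound by at least two factors — the two views (per-region and
#' per-peak) the co-occupancy analysis needs.
#'
#' @param peaksets Named list of interval tibbles, one per factor.
#' @param state_map Optional `chromatin_state_map` for state annotation.
#' @return A `cobinding_table`: `$regions` (union regions with one logical
#'   column per factor, `n_tfs_bound`, `state`) and `$per_tf`
#'   (n_peaks, n_cobound, prop_cobound).
#' @export
count_cobinding <- function(peaksets, state_map = NULL) {
  stopifnot(is.list(peaksets), !is.null(names(peaksets)))
  peaksets <- lapply(peaksets, as_intervals)
  nonempty <- vapply(peaksets, nrow, integer(1)) > 0
  if (!any(nonempty)) stop("need at least one nonempty peak set")
  all_peaks <- dplyr::bind_rows(lapply(peaksets, function(p) {
    p[, c("chrom", "start", "end")]
  }))
  union <- merge_intervals(all_peaks, gap = 0)
  regions <- union[, c("chrom", "start", "end")]
  for (tf in names(peaksets)) {
    regions[[tf]] <- overlaps_any(regions, peaksets[[tf]])
  }
  regions$n_tfs_bound <- rowSums(as.matrix(regions[, names(peaksets)]))
  regions$state <- if (!is.null(state_map)) {
    annotate_state(regions[, c("chrom", "start", "end")], state_map)
  } else "none"
  per_tf <- purrr::map_dfr(names(peaksets), function(tf) {
    p <- peaksets[[tf]]
    cob <- regions[regions$n_tfs_bound >= 2, c("chrom", "start", "end")]
    in_cob <- if (nrow(p) > 0) overlaps_any(p, cob) else logical(0)
    tibble::tibble(tf = tf, n_peaks = nrow(p), n_cobound = sum(in_cob),
                   prop_cobound = ifelse(nrow(p) > 0, mean(in_cob), NA_real_))
  })
  structure(list(regions = regions, per_tf = per_tf),
            class = "cobinding_table")
}

#' @export
print.cobinding_table <- function(x, ...) {
  cat("Co-binding over", nrow(x$regions), "union regions\n")
  print(table(n_tfs_bound = x$regions$n_tfs_bound))
  invisible(x)
}

#' Tidy a co-binding table into its union regions
#' @param x A `cobinding_table`.
#' @param ... Unused.
#' @export
tidy.cobinding_table <- function(x, ...) tibble::as_tibble(x$regions)

#' One-row summary of a co-binding table
#' @param x A `cobinding_table`.
#' @param ... Unused.
#' @export
glance.cobinding_table <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x$regions),
                 n_all_four = sum(x$regions$n_tfs_bound ==
                                    nrow(x$per_tf)),
                 prop_regions_cobound = mean(x$regions$n_tfs_bound >= 2))
}

#' Stacked-bar plot of chromatin state by co-binding degree
#' @param object A `cobinding_table`.
#' @param ... Unused.
#' @export
autoplot.cobinding_table <- function(object, ...) {
  df <- dplyr::count(object$regions, .data$n_tfs_bound, .data$state)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$n_tfs_bound),
                                   y = .data$n, fill = .data$state)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = "number of TFs bound", y = "fraction of regions",
                  fill = "chromatin state") +
    ggplot2::theme_minimal()
}

#' Compare one factor's cistrome between two cellular contexts
#'
#' A peak is common when it overlaps at least one peak of the other
#' context; common regions are reported as the gap-0 merge of all
#' reciprocally overlapping peaks (one count of shared regions), and
#' `fraction_common = common / (common + specific_A + specific_B)`.
#'
#' @param peaks_a,peaks_b Interval tibbles for the same factor in contexts
#'   A and B.
#' @param labels Length-2 labels for the contexts.
#' @return A list: `summary` (one-row tibble with the counts and
#'   `fraction_common`) and `peaks` (every input peak labelled
#'   specific_a / specific_b / common, plus merged `common_regions`).
#' @export
compare_contexts <- function(peaks_a, peaks_b, labels = c("A", "B")) {
  peaks_a <- as_intervals(peaks_a)
  peaks_b <- as_intervals(peaks_b)
  com_a <- overlaps_any(peaks_a, peaks_b)
  com_b <- overlaps_any(peaks_b, peaks_a)
  common_peaks <- dplyr::bind_rows(peaks_a[com_a, c("chrom", "start", "end")],
                                   peaks_b[com_b, c("chrom", "start", "end")])
  common_regions <- if (nrow(common_peaks) > 0) {
    merge_intervals(common_peaks, gap = 0)
  } else common_peaks
  n_common <- nrow(common_regions)
  n_spec_a <- sum(!com_a)
  n_spec_b <- sum(!com_b)
  denom <- n_common + n_spec_a + n_spec_b
  peaks <- dplyr::bind_rows(
    dplyr::mutate(peaks_a[, c("chrom", "start", "end")],
                  context = labels[1],
                  class = ifelse(com_a, "common", "specific_a")),
    dplyr::mutate(peaks_b[, c("chrom", "start", "end")],
                  context = labels[2],
                  class = ifelse(com_b, "common", "specific_b")))
  list(summary = tibble::tibble(
    specific_a = n_spec_a, specific_b = n_spec_b, common = n_common,
    fraction_common = ifelse(denom > 0, n_common / denom, NA_real_)),
    peaks = peaks, common_regions = common_regions)
}

#' Permutation test for TF binding enrichment at enhancers
#'
#' The observed statistic is the fraction of enhancers overlapping at least
#' one peak of any supplied factor. The null relocates each enhancer
#' uniformly at random within its own chromosome, preserving its length
#' (placements independent; overlaps among relocated enhancers allowed),
#' and recomputes the statistic. The empirical p-value is
#' `(1 + #\{null >= observed\}) / (n_permutations + 1)`, never zero. Also
#' reports the observed distribution of enhancers bound by k = 0..K
#' factors.
#'
#' @param enhancers Interval tibble.
#' @param peaksets Named list of per-factor interval tibbles.
#' @param genome Genome layout ([genome_layout()]).
#' @param n_permutations Number of permutations (default 9,999 so the
#'   smallest attainable p is 1e-4).
#' @param seed Integer seed; results are reproducible given it.
#' @return A `perm_test` object.
#' @export
enhancer_binding_permutation <- function(enhancers, peaksets, genome,
                                         n_permutations = 9999, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  enhancers <- as_intervals(enhancers, genome = genome)
  if (nrow(enhancers) == 0) stop("no enhancers supplied")
  peaksets <- lapply(peaksets, as_intervals)
  union <- merge_intervals(
    dplyr::bind_rows(lapply(peaksets, function(p) p[, c("chrom", "start", "end")])),
    gap = 0)

  bound_mat <- vapply(peaksets, function(p) overlaps_any(enhancers, p),
                      logical(nrow(enhancers)))
  if (is.null(dim(bound_mat))) bound_mat <- matrix(bound_mat, nrow = 1)
  k_bound <- rowSums(bound_mat)
  observed <- mean(k_bound >= 1)
  bound_by_k <- tibble::tibble(k = 0:length(peaksets),
                               n = vapply(0:length(peaksets), function(k) {
                                 sum(k_bound == k)
                               }, numeric(1))) |>
    dplyr::mutate(ratio = .data$n / nrow(enhancers))

  lens <- enhancers$end - enhancers$start
  chrom_len <- genome$length[match(enhancers$chrom, genome$chrom)]
  if (any(lens > chrom_len)) stop("enhancer longer than its chromosome")

  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  null_hits <- numeric(n_permutations)
  for (i in seq_len(nrow(enhancers))) {
    u <- union[union$chrom == enhancers$chrom[i], ]
    max_start <- chrom_len[i] - lens[i]
    starts <- floor(stats::runif(n_permutations) * (max_start + 1))
    if (nrow(u) == 0) next
    # start s overlaps a union interval [a,b) iff s in [a - L + 1, b - 1],
    # i.e. s < b and s > a - L; expand, merge, then test by findInterval
    es <- pmax(u$start - lens[i] + 1, 0)
    ee <- u$end
    keep <- ee > es
    es <- es[keep]; ee <- ee[keep]
    if (!length(es)) next
    e_run <- cummax(ee)
    gidx <- which(c(TRUE, es[-1] > e_run[-length(ee)]))
    merged_s <- es[gidx]
    merged_e <- e_run[c(gidx[-1] - 1, length(ee))]
    flat <- as.vector(rbind(merged_s, merged_e))
    inside <- findInterval(starts, flat) %% 2 == 1
    null_hits <- null_hits + inside
  }
  null_draws <- null_hits / nrow(enhancers)
  p <- (1 + sum(null_draws >= observed)) / (n_permutations + 1)
  structure(list(observed = observed, null_draws = null_draws,
                 p_value = p, n_permutations = n_permutations,
                 n_enhancers = nrow(enhancers), seed = seed,
                 bound_by_k = bound_by_k,
                 null_model = "length-preserving uniform relocation within chromosome"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation enrichment test (%d enhancers, N = %d)\n",
              x$n_enhancers, x$n_permutations))
  cat(sprintf("  observed fraction bound: %.4f\n", x$observed))
  cat(sprintf("  null mean: %.4f  empirical P = %.3g\n",
              mean(x$null_draws), x$p_value))
  invisible(x)
}

#' Tidy the bound-by-k distribution of a permutation test
#' @param x A `perm_test`.
#' @param ... Unused.
#' @export
tidy.perm_test <- function(x, ...) x$bound_by_k

#' One-row summary of a permutation test
#' @param x A `perm_test`.
#' @param ... Unused.
#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, null_mean = mean(x$null_draws),
                 null_sd = stats::sd(x$null_draws), p_value = x$p_value,
                 n_permutations = x$n_permutations,
                 n_enhancers = x$n_enhancers)
}

#' Null-distribution plot for a permutation test
#' @param object A `perm_test`.
#' @param ... Unused.
#' @export
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(stat = object$null_draws),
                  ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = "fraction of enhancers bound (null)", y = "count",
                  subtitle = sprintf("observed = %.3f, P = %.2g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Binned signal matrix around region centers
#'
#' Computes the mean track signal in fixed-width bins across a window
#' centered on each region's midpoint, scaled to counts-per-million by
#' `1e6 / library_size`. Row order follows the sorted center regions, so
#' rows are directly comparable across tracks.
#'
#' @param track bedGraph tibble from [read_bedgraph()] (`chrom`, `start`,
#'   `end`, `value`).
#' @param centers Interval tibble; windows are placed on midpoints.
#' @param window Full window width, bp; must be divisible by `bin`.
#' @param bin Bin width, bp.
#' @param library_size Total read count used for CPM scaling.
#' @param genome Optional layout; windows extending beyond a chromosome are
#'   zero-padded and flagged.
#' @return A numeric matrix (regions x bins) with attribute `clipped`, a
#'   logical vector marking rows whose window ran off a chromosome edge.
#' @export
signal_matrix <- function(track, centers, window = 3000, bin = 50,
                          library_size = 1e6, genome = NULL) {
  if (window %% bin != 0) stop("window must be divisible by bin")
  centers <- as_intervals(centers)
  nb <- window %/% bin
  n <- nrow(centers)
  mat <- matrix(0, n, nb)
  if (n == 0) return(structure(mat, clipped = logical(0)))
  mid <- (centers$start + centers$end) %/% 2
  win_start <- mid - window %/% 2
  clipped <- win_start < 0
  if (!is.null(genome)) {
    clen <- genome$length[match(centers$chrom, genome$chrom)]
    clipped <- clipped | (win_start + window > clen)
  }
  bins <- tibble::tibble(
    row = rep(seq_len(n), each = nb),
    col = rep(seq_len(nb), times = n),
    chrom = rep(centers$chrom, each = nb),
    start = rep(win_start, each = nb) + (rep(seq_len(nb), times = n) - 1) * bin,
    end = rep(win_start, each = nb) + rep(seq_len(nb), times = n) * bin)
  bins <- bins[bins$end > 0, ]
  bins$start <- pmax(bins$start, 0)
  bins <- as_intervals(bins)
  track <- as_intervals(track)
  ov <- overlap_pairs(bins, track)
  if (nrow(ov) > 0) {
    contrib <- ov$overlap_bp * track$value[ov$idx_b] / bin
    idx <- cbind(bins$row[ov$idx_a], bins$col[ov$idx_a])
    agg <- tapply(contrib, paste(idx[, 1], idx[, 2]), sum)
    key <- do.call(rbind, strsplit(names(agg), " "))
    mat[cbind(as.integer(key[, 1]), as.integer(key[, 2]))] <- as.numeric(agg)
  }
  mat <- mat * 1e6 / library_size
  structure(mat, clipped = clipped)
}
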