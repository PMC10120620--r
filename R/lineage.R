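# Tissue-panel analyses: clustering tissues on master-TF expression,
# ranking tissues by average pairwise TF correlation, and IHC
# co-positivity scoring.

TF_COLS <- c("MECOM", "PAX8", "SOX17", "WT1")

#' Cluster tissues on master-TF expression profiles
#'
#' Computes per-tissue mean profiles over the four TF columns, z-scores
#' each TF across tissues, and clusters with k-means (20 restarts, best
#' inertia kept; deterministic given `seed`). Hierarchical clustering
#' (Ward on Euclidean distances, cut at k) is available as an option.
#'
#' @param expr Tibble: `sample`, `tissue`, and the four TF columns on a
#'   log-expression scale.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed for the k-means restarts.
#' @param method `"kmeans"` (default) or `"hierarchical"`.
#' @return A `tissue_clusters` object: `$clusters` (tissue, cluster),
#'   `$centers` (per-cluster mean z-profile), `$method`.
#' @export
cluster_tissues <- function(expr, k = 5, seed = 1, method = c("kmeans", "hierarchical")) {
  method <- match.arg(method)
  stopifnot(all(c("tissue", TF_COLS) %in% names(expr)))
  prof <- expr |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(TF_COLS), mean),
                     .groups = "drop")
  if (k > nrow(prof)) stop("k exceeds the number of tissues")
  z <- scale(as.matrix(prof[, TF_COLS]))
  if (any(!is.finite(z))) {
    warning("constant expression across tissues for some TF; z-scores degenerate")
    z[!is.finite(z)] <- 0
  }
  n_distinct_prof <- nrow(unique(z))
  if (n_distinct_prof < k) {
    warning("fewer distinct tissue profiles than clusters; ",
            "tissues collapse onto ", n_distinct_prof, " effective profile(s)")
    cl <- as.integer(factor(apply(z, 1, paste, collapse = "/"),
                            levels = unique(apply(z, 1, paste, collapse = "/"))))
    centers <- unique(z)
  } else if (k == nrow(prof)) {
    # degenerate but well-defined: every tissue is its own cluster
    cl <- seq_len(nrow(prof))
    centers <- z
  } else if (method == "kmeans") {
    set.seed(as.integer(seed))
    km <- stats::kmeans(z, centers = k, nstart = 20, iter.max = 50)
    cl <- km$cluster
    centers <- km$centers
  } else {
    hc <- stats::hclust(stats::dist(z), method = "ward.D2")
    cl <- stats::cutree(hc, k = k)
    centers <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
      colMeans(z[cl == g, , drop = FALSE])
    }))
  }
  structure(list(
    clusters = tibble::tibble(tissue = prof$tissue, cluster = unname(cl)),
    centers = tibble::as_tibble(centers, .name_repair = "minimal") |>
      dplyr::mutate(cluster = seq_len(nrow(centers)), .before = 1),
    method = method, k = k), class = "tissue_clusters")
}

#' Tidy tissue clusters
#' @param x A `tissue_clusters`.
#' @param ... Unused.
#' @export
tidy.tissue_clusters <- function(x, ...) x$clusters

#' One-row clustering summary
#' @param x A `tissue_clusters`.
#' @param ... Unused.
#' @export
glance.tissue_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, method = x$method,
                 n_tissues = nrow(x$clusters),
                 largest_cluster = max(table(x$clusters$cluster)))
}

#' Rank tissues by average pairwise TF correlation
#'
#' For each tissue, the Pearson correlation of every one of the six TF
#' pairs is computed across that tissue's samples and the tissue is ranked
#' by the mean of the six values (descending; ties broken alphabetically
#' and flagged). A zero-variance TF makes its pairs undefined; the mean is
#' then taken over the defined pairs and the tissue flagged.
#'
#' @param expr Tibble as in [cluster_tissues()]; tissues with fewer than 3
#'   samples are dropped with a warning.
#' @return Tibble: `tissue`, `mean_r`, `n_pairs_defined`, `rank`,
#'   `tie_flag`, `variance_flag`, ordered by rank.
#' @export
rank_by_correlation <- function(expr) {
  stopifnot(all(c("tissue", TF_COLS) %in% names(expr)))
  sizes <- table(expr$tissue)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("dropping tissue(s) with < 3 samples: ",
            paste(small, collapse = ", "))
    expr <- expr[!expr$tissue %in% small, ]
  }
  pairs <- utils::combn(TF_COLS, 2)
  out <- purrr::map_dfr(sort(unique(expr$tissue)), function(ts) {
    m <- as.matrix(expr[expr$tissue == ts, TF_COLS])
    rs <- vapply(seq_len(ncol(pairs)), function(p) {
      a <- m[, pairs[1, p]]; b <- m[, pairs[2, p]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
    tibble::tibble(tissue = ts, mean_r = mean(rs, na.rm = TRUE),
                   n_pairs_defined = sum(!is.na(rs)),
                   variance_flag = anyNA(rs))
  })
  out <- out[order(-out$mean_r, out$tissue), ]
  out$rank <- seq_len(nrow(out))
  out$tie_flag <- duplicated(out$mean_r) | duplicated(out$mean_r, fromLast = TRUE)
  out
}

#' Score IHC co-positivity of the four factors
#'
#' A factor is positive in a sample when its positivity rate meets the
#' threshold (inclusive). Returns per-sample counts and, per histotype, the
#' fraction of samples with 0..4 positive factors and the fraction
#' co-staining for all four.
#'
#' @param tab Tibble: `sample`, `histotype`, four TF rate columns in `[0,1]`.
#' @param threshold Positivity-rate threshold (default 0.1).
#' @return A list: `per_sample` (sample, histotype, n_positive) and
#'   `per_histotype` (histotype, n_positive, fraction; fractions sum to 1
#'   within each histotype) plus `co_stain_all4` per histotype.
#' @export
co_positivity <- function(tab, threshold = 0.1) {
  stopifnot(all(c("histotype", TF_COLS) %in% names(tab)))
  rates <- as.matrix(tab[, TF_COLS])
  if (any(rates < 0 | rates > 1)) stop("positivity rates must lie in [0, 1]")
  per_sample <- tibble::tibble(
    sample = if ("sample" %in% names(tab)) tab$sample else
      sprintf("s%03d", seq_len(nrow(tab))),
    histotype = tab$histotype,
    n_positive = rowSums(rates >= threshold))
  per_histotype <- per_sample |>
    dplyr::count(.data$histotype, .data$n_positive) |>
    tidyr::complete(.data$histotype, n_positive = 0:4, fill = list(n = 0L)) |>
    dplyr::group_by(.data$histotype) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  co_all4 <- per_sample |>
    dplyr::group_by(.data$histotype) |>
    dplyr::summarise(co_stain_all4 = mean(.data$n_positive == 4),
                     .groups = "drop")
  list(per_sample = per_sample, per_histotype = per_histotype,
       co_stain_all4 = co_all4)
}
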