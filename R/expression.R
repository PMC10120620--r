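# Spike-in-anchored normalization of knockdown RNA-seq and the
# effect-size ("high-confidence") differential-expression rule.

count_cols <- function(counts) {
  setdiff(names(counts), c("gene_id", "length", "is_spikein"))
}

#' Transcripts per million
#'
#' Per sample: `rate_g = count_g / length_kb_g`, `TPM_g = 1e6 * rate_g /
#' sum(rates)`; every column sums to one million. Gene lengths must be
#' positive; an all-zero sample yields an all-zero column with a warning.
#'
#' @param counts Count tibble: `gene_id`, `length` (bp), `is_spikein`, one
#'   numeric column per sample.
#' @return The same tibble with counts replaced by TPM values.
#' @export
tpm <- function(counts) {
  stopifnot(all(c("gene_id", "length") %in% names(counts)))
  if (any(counts$length <= 0)) stop("gene lengths must be > 0")
  sc <- count_cols(counts)
  rate <- as.matrix(counts[, sc]) / (counts$length / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero sample(s): ", paste(sc[tot == 0], collapse = ", "))
    tot[tot == 0] <- 1
  }
  out <- counts
  out[, sc] <- sweep(rate, 2, tot, "/") * 1e6
  out
}

#' Cyclic loess normalization anchored on spike-ins
#'
#' Works on `log2(TPM + pseudocount)`. For every sample pair, a local
#' linear smoother of M (log-ratio) against A (log-mean) is fitted on the
#' anchor rows only and half the fitted M is subtracted from one sample and
#' added to the other — applied to all rows. Passes repeat until the
#' largest absolute median anchor M across pairs drops below `tol`, or
#' `max_pass` passes.
#'
#' With `anchor = "spikeins_only"` a global shift that the spike-ins track
#' (a technical distortion affecting them too) is removed, whereas a shift
#' confined to genes while spike-ins are untouched is preserved — the
#' spike-ins certify it as biological. This is the property that lets the
#' pipeline see genuine global transcriptional shifts after knockdown.
#'
#' @param tpm_tbl TPM tibble from [tpm()].
#' @param anchor `"spikeins_only"` (default; requires >= 20 spike-in rows
#'   nonzero in every sample) or `"all_genes"`.
#' @param span Smoother span (default 0.6).
#' @param pseudocount Added on the TPM scale before log2 (default 1).
#' @param tol Convergence tolerance on the median anchor M (default 0.01).
#' @param max_pass Maximum number of passes (default 3).
#' @return The tibble with sample columns replaced by normalized TPM.
#' @export
loess_normalize <- function(tpm_tbl, anchor = c("spikeins_only", "all_genes"),
                            span = 0.6, pseudocount = 1, tol = 0.01,
                            max_pass = 3) {
  anchor <- match.arg(anchor)
  sc <- count_cols(tpm_tbl)
  if (length(sc) < 2) stop("need at least 2 samples")
  mat <- log2(as.matrix(tpm_tbl[, sc]) + pseudocount)
  if (anchor == "spikeins_only") {
    if (!"is_spikein" %in% names(tpm_tbl)) stop("no is_spikein column")
    raw <- as.matrix(tpm_tbl[tpm_tbl$is_spikein, sc, drop = FALSE])
    ok <- tpm_tbl$is_spikein
    ok[ok] <- rowSums(raw > 0) == length(sc)
    if (sum(ok) < 20) {
      stop("insufficient anchor rows: need >= 20 spike-ins nonzero in all samples")
    }
    anchor_rows <- which(ok)
  } else {
    anchor_rows <- seq_len(nrow(tpm_tbl))
  }
  ns <- length(sc)
  pairs <- utils::combn(ns, 2)
  # each pass fits every pair from the pass-start matrix and gives sample i
  # the mean of its fitted pairwise offsets: a constant shift is removed
  # exactly in one pass and smoother noise does not accumulate across pairs
  for (pass in seq_len(max_pass)) {
    adj <- matrix(0, nrow(mat), ns)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      M <- mat[, i] - mat[, j]
      A <- (mat[, i] + mat[, j]) / 2
      fit <- stats::lowess(A[anchor_rows], M[anchor_rows], f = span)
      pred <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
      adj[, i] <- adj[, i] + pred
      adj[, j] <- adj[, j] - pred
    }
    mat <- mat - adj / ns
    worst <- max(vapply(seq_len(ncol(pairs)), function(p) {
      abs(stats::median(mat[anchor_rows, pairs[1, p]] -
                          mat[anchor_rows, pairs[2, p]]))
    }, numeric(1)))
    if (worst < tol) break
  }
  out <- tpm_tbl
  out[, sc] <- pmax(2^mat - pseudocount, 0)
  out
}

#' TPM plus spike-in-anchored normalization, per cell line
#'
#' Convenience wrapper running [tpm()] and then [loess_normalize()] within
#' each cell line separately, so every line is anchored on its own
#' spike-in measurements (fold changes are always computed within a line).
#'
#' @param counts Count tibble (see [tpm()]).
#' @param samples Sample metadata (`sample`, `cell_line`).
#' @param ... Passed to [loess_normalize()].
#' @return Normalized TPM tibble.
#' @export
normalize_counts <- function(counts, samples, ...) {
  tp <- tpm(counts)
  out <- tp
  for (cl in unique(samples$cell_line)) {
    cols <- samples$sample[samples$cell_line == cl]
    sub <- tp[, c(intersect(c("gene_id", "length", "is_spikein"), names(tp)),
                  cols)]
    out[, cols] <- loess_normalize(sub, ...)[, cols]
  }
  out
}

#' Per-gene, per-cell-line log2 fold change for one knockdown
#'
#' `log2fc = mean over knockdown replicates of log2(TPM + pc) - mean over
#' the pooled replicates of both control conditions of log2(TPM + pc)`,
#' computed independently within each cell line.
#'
#' @param norm Normalized TPM tibble.
#' @param samples Sample metadata (`sample`, `cell_line`, `context`,
#'   `condition`, `replicate`).
#' @param tf Factor name (`"PAX8"`) or condition (`"siPAX8"`).
#' @param controls The two control condition labels (pooled).
#' @param pseudocount Added before log2.
#' @return Tibble: `gene_id`, `tf`, `cell_line`, `context`, `log2fc`.
#' @export
log2fc <- function(norm, samples, tf, controls = c("control_1", "control_2"),
                   pseudocount = 1) {
  cond <- if (startsWith(tf, "si")) tf else paste0("si", tf)
  tf_name <- sub("^si", "", cond)
  if (!cond %in% samples$condition) stop("condition not present: ", cond)
  if (!all(controls %in% samples$condition)) {
    stop("control condition(s) missing: ",
         paste(setdiff(controls, samples$condition), collapse = ", "))
  }
  sc <- count_cols(norm)
  mat <- log2(as.matrix(norm[, sc]) + pseudocount)
  purrr::map_dfr(unique(samples$cell_line), function(cl) {
    kd <- samples$sample[samples$cell_line == cl & samples$condition == cond]
    ct <- samples$sample[samples$cell_line == cl &
                           samples$condition %in% controls]
    if (!length(kd) || !length(ct)) {
      stop("cell line ", cl, " lacks knockdown or control samples")
    }
    tibble::tibble(
      gene_id = norm$gene_id, tf = tf_name, cell_line = cl,
      context = samples$context[samples$cell_line == cl][1],
      log2fc = rowMeans(mat[, kd, drop = FALSE]) -
        rowMeans(mat[, ct, drop = FALSE]))
  })
}

#' Log2 fold changes for every knockdown condition present
#'
#' @inheritParams log2fc
#' @param tfs Factors to process (default: every `si*` condition found).
#' @return Row-bound [log2fc()] tables.
#' @export
log2fc_table <- function(norm, samples, tfs = NULL,
                         controls = c("control_1", "control_2"),
                         pseudocount = 1) {
  if (is.null(tfs)) {
    tfs <- sub("^si", "", grep("^si", unique(samples$condition), value = TRUE))
  }
  purrr::map_dfr(tfs, function(tf) {
    log2fc(norm, samples, tf, controls = controls, pseudocount = pseudocount)
  })
}

#' Call high-confidence differentially expressed genes
#'
#' A gene is a high-confidence target of a factor in a context when its
#' absolute log2 fold change meets `threshold` in both cell lines of that
#' context with the same sign (the inclusive `>=` rule). Direction is the
#' sign of the mean fold change.
#'
#' @param lfc Long table from [log2fc_table()] (`gene_id`, `tf`,
#'   `cell_line`, `context`, `log2fc`).
#' @param threshold Absolute log2FC threshold (default 0.5).
#' @param allow_single Allow contexts with a single cell line (the flag
#'   then reflects that one line).
#' @return A `deg_table` tibble: `gene_id`, `tf`, `context`, per-line
#'   `log2fc_1`/`log2fc_2`, `mean_log2fc`, `high_confidence`, `direction`.
#' @export
call_high_confidence <- function(lfc, threshold = 0.5, allow_single = FALSE) {
  stopifnot(all(c("gene_id", "tf", "cell_line", "context", "log2fc") %in%
                  names(lfc)))
  nl <- lfc |>
    dplyr::distinct(.data$context, .data$cell_line) |>
    dplyr::count(.data$context)
  if (any(nl$n != 2) && !allow_single) {
    stop("each context needs exactly two cell lines (allow_single = TRUE to override)")
  }
  out <- lfc |>
    dplyr::group_by(.data$gene_id, .data$tf, .data$context) |>
    dplyr::arrange(.data$cell_line, .by_group = TRUE) |>
    dplyr::summarise(
      log2fc_1 = .data$log2fc[1],
      log2fc_2 = ifelse(dplyr::n() > 1, .data$log2fc[2], NA_real_),
      mean_log2fc = mean(.data$log2fc),
      high_confidence = all(abs(.data$log2fc) >= threshold) &
        (dplyr::n_distinct(sign(.data$log2fc)) == 1),
      .groups = "drop") |>
    dplyr::mutate(direction = ifelse(.data$mean_log2fc >= 0, "up", "down"))
  class(out) <- c("deg_table", class(out))
  out
}
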