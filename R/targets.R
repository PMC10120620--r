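# TAD-aware classification of TF target genes (direct / putative /
# indirect) and the signed core-regulatory circuit among the factors.

#' Read a TAD table
#'
#' Accepts a 3-column tabular file (chrom, start, end) or a BEDPE-style
#' domain file (anchors on the same chromosome; the domain spans from the
#' first anchor start to the second anchor end).
#'
#' @param path Path to the TAD file.
#' @return TAD tibble (`chrom`, `start`, `end`, `tad_id`).
#' @export
read_tads <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"), comment = "#")
  if (nrow(raw) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), tad_id = character()))
  }
  if (ncol(raw) >= 6 &&
      all(!is.na(suppressWarnings(as.numeric(raw[[5]]))))) {
    loops <- read_bedpe(path)
    if (any(loops$chrom1 != loops$chrom2)) {
      stop("TAD BEDPE anchors must share a chromosome")
    }
    out <- tibble::tibble(chrom = loops$chrom1, start = loops$start1,
                          end = loops$end2)
  } else {
    out <- tibble::tibble(chrom = raw[[1]],
                          start = suppressWarnings(as.numeric(raw[[2]])),
                          end = suppressWarnings(as.numeric(raw[[3]])))
    if (any(is.na(out$start) | is.na(out$end))) stop("malformed TAD table")
  }
  out <- as_intervals(out)
  out$tad_id <- sprintf("tad_%02d", seq_len(nrow(out)))
  out
}

# smallest TAD containing each TSS (nested input domains are legal; the
# smallest containing domain scopes the gene)
gene_tad_interval <- function(genes, tads) {
  g <- tibble::tibble(chrom = genes$chrom, start = genes$tss,
                      end = genes$tss + 1)
  hits <- GenomicRanges::findOverlaps(iv_to_gr(g), iv_to_gr(tads))
  hit_df <- tibble::tibble(gi = S4Vectors::queryHits(hits),
                           ti = S4Vectors::subjectHits(hits))
  hit_df$width <- tads$end[hit_df$ti] - tads$start[hit_df$ti]
  best <- hit_df |>
    dplyr::group_by(.data$gi) |>
    dplyr::slice_min(.data$width, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- tibble::tibble(gene_id = genes$gene_id,
                        tad_start = NA_real_, tad_end = NA_real_,
                        tad_id = NA_character_)
  out$tad_start[best$gi] <- tads$start[best$ti]
  out$tad_end[best$gi] <- tads$end[best$ti]
  if ("tad_id" %in% names(tads)) out$tad_id[best$gi] <- tads$tad_id[best$ti]
  out
}

#' Classify high-confidence DEGs as direct, putative or indirect targets
#'
#' Implements the three-way integration of differential expression, TF
#' binding and TAD maps: a DEG is a *direct* target when a peak of the
#' knocked-down factor overlaps the gene's promoter (TSS +/-
#' `promoter_window`); otherwise *putative* when the factor has a peak
#' within the TAD containing the gene's TSS; otherwise *indirect*.
#' Precedence direct > putative > indirect, so every high-confidence DEG
#' receives exactly one mode per factor. Genes whose TSS lies in no TAD can
#' still be direct via promoter overlap, otherwise indirect.
#'
#' @param deg A `deg_table` from [call_high_confidence()]; only
#'   `high_confidence` rows of the requested context are classified.
#' @param peaks Long peak tibble for one context (`tf`, `chrom`, `start`,
#'   `end`, optional `locus_id`), or named list of per-factor tibbles.
#' @param genes Gene models (`gene_id`, `chrom`, `tss`).
#' @param tads TAD tibble (`chrom`, `start`, `end`); may contain nested
#'   domains (smallest containing domain wins).
#' @param context Context label to classify.
#' @param promoter_window Promoter half-width, bp; shared with
#'   [build_state_map()] so promoter and non-promoter are complementary.
#' @return A tibble of target calls: `tf`, `gene_id`, `context`, `mode`,
#'   `sign`, `evidence` (supporting peak ids or `"none"`).
#' @export
classify_targets <- function(deg, peaks, genes, tads, context,
                             promoter_window = 2000) {
  if (is.list(peaks) && !is.data.frame(peaks)) {
    peaks <- dplyr::bind_rows(purrr::imap(peaks, function(p, nm) {
      dplyr::mutate(p, tf = nm)
    }))
  }
  hc <- deg[deg$high_confidence & deg$context == context, ]
  missing <- setdiff(unique(hc$gene_id), genes$gene_id)
  if (length(missing)) {
    warning("skipping ", length(missing), " DEG(s) missing from gene models")
    hc <- hc[!hc$gene_id %in% missing, ]
  }
  if (nrow(hc) == 0) {
    return(tibble::tibble(tf = character(), gene_id = character(),
                          context = character(), mode = character(),
                          sign = character(), evidence = character()))
  }
  gt <- gene_tad_interval(genes, tads)
  purrr::map_dfr(unique(hc$tf), function(tf) {
    sub <- hc[hc$tf == tf, ]
    p <- peaks[peaks$tf == tf, ]
    pid <- if ("locus_id" %in% names(p)) p$locus_id else
      sprintf("peak_%04d", seq_len(nrow(p)))
    g <- genes[match(sub$gene_id, genes$gene_id), ]
    ti <- gt[match(sub$gene_id, gt$gene_id), ]
    mode <- character(nrow(sub))
    evidence <- rep("none", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      prom_s <- max(g$tss[i] - promoter_window, 0)
      prom_e <- g$tss[i] + promoter_window
      on_chrom <- p$chrom == g$chrom[i]
      at_prom <- on_chrom & p$start < prom_e & p$end > prom_s
      if (any(at_prom)) {
        mode[i] <- "direct"
        evidence[i] <- paste(pid[at_prom], collapse = ",")
      } else if (!is.na(ti$tad_start[i])) {
        in_tad <- on_chrom & p$start < ti$tad_end[i] & p$end > ti$tad_start[i]
        if (any(in_tad)) {
          mode[i] <- "putative"
          evidence[i] <- paste(pid[in_tad], collapse = ",")
        } else mode[i] <- "indirect"
      } else mode[i] <- "indirect"
    }
    tibble::tibble(tf = tf, gene_id = sub$gene_id, context = context,
                   mode = mode, sign = sub$direction, evidence = evidence)
  }) |>
    dplyr::arrange(.data$tf, .data$gene_id)
}

#' Summarize target rewiring between two contexts
#'
#' @param calls_a,calls_b Target-call tibbles from [classify_targets()] for
#'   the same factors in two contexts.
#' @return A list: `per_tf` (genes exclusive to each context and shared)
#'   and `transitions` (for shared genes, counts of each mode pair).
#' @export
rewiring_summary <- function(calls_a, calls_b) {
  tfs <- union(unique(calls_a$tf), unique(calls_b$tf))
  per_tf <- purrr::map_dfr(tfs, function(tf) {
    ga <- calls_a$gene_id[calls_a$tf == tf]
    gb <- calls_b$gene_id[calls_b$tf == tf]
    tibble::tibble(tf = tf, exclusive_a = length(setdiff(ga, gb)),
                   exclusive_b = length(setdiff(gb, ga)),
                   shared = length(intersect(ga, gb)))
  })
  transitions <- dplyr::inner_join(
    calls_a[, c("tf", "gene_id", "mode")],
    calls_b[, c("tf", "gene_id", "mode")],
    by = c("tf", "gene_id"), suffix = c("_a", "_b")) |>
    dplyr::count(.data$tf, .data$mode_a, .data$mode_b)
  list(per_tf = per_tf, transitions = transitions)
}

#' Build the core-regulatory circuit among the factors
#'
#' For every high-confidence effect of one factor's knockdown on another
#' factor's gene (self-edges, i.e. autoregulation, allowed), draws a signed
#' directed edge: the regulator *activates* a target that goes down on
#' knockdown and *represses* one that goes up.
#'
#' @param deg A `deg_table` from [call_high_confidence()].
#' @param tf_genes Gene ids of the factor loci (default the four master TFs).
#' @return A `tf_circuit` object with `$edges` (regulator, target, context,
#'   sign, mean_log2fc) and `$nodes`.
#' @export
build_circuit <- function(deg, tf_genes = c("MECOM", "PAX8", "SOX17", "WT1")) {
  edges <- deg |>
    dplyr::filter(.data$gene_id %in% tf_genes, .data$high_confidence) |>
    dplyr::transmute(regulator = .data$tf, target = .data$gene_id,
                     context = .data$context,
                     sign = ifelse(.data$direction == "down",
                                   "activates", "represses"),
                     mean_log2fc = .data$mean_log2fc)
  structure(list(edges = tibble::as_tibble(edges), nodes = tf_genes),
            class = "tf_circuit")
}

#' @export
print.tf_circuit <- function(x, ...) {
  cat("Core-regulatory circuit:", nrow(x$edges), "edges among",
      length(x$nodes), "factors\n")
  print(x$edges, n = 20)
  invisible(x)
}

#' Tidy circuit edges
#' @param x A `tf_circuit`.
#' @param ... Unused.
#' @export
tidy.tf_circuit <- function(x, ...) x$edges

#' One-row circuit summary
#' @param x A `tf_circuit`.
#' @param ... Unused.
#' @export
glance.tf_circuit <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x$edges),
                 n_activating = sum(x$edges$sign == "activates"),
                 n_repressing = sum(x$edges$sign == "represses"),
                 n_autoregulatory = sum(x$edges$regulator == x$edges$target))
}

#' Node-and-edge plot of a core-regulatory circuit
#' @param object A `tf_circuit`.
#' @param ... Unused.
#' @export
autoplot.tf_circuit <- function(object, ...) {
  nodes <- tibble::tibble(
    name = object$nodes,
    angle = seq(0, 2 * pi, length.out = length(object$nodes) + 1)[-1])
  nodes$x <- cos(nodes$angle)
  nodes$y <- sin(nodes$angle)
  ed <- object$edges |>
    dplyr::left_join(nodes[, c("name", "x", "y")],
                     by = c(regulator = "name")) |>
    dplyr::left_join(nodes[, c("name", "x", "y")],
                     by = c(target = "name"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_curve(
      data = ed[ed$regulator != ed$target, ],
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                   yend = .data$y_to, colour = .data$sign),
      curvature = 0.15,
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches"))) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 10,
                        colour = "grey85") +
    ggplot2::geom_text(data = nodes, ggplot2::aes(.data$x, .data$y,
                                                  label = .data$name)) +
    ggplot2::scale_colour_manual(values = c(activates = "steelblue",
                                            represses = "firebrick")) +
    ggplot2::facet_wrap(~context) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.4, 1.4)) +
    ggplot2::theme_void()
}

#' Write a circuit as DOT-format text
#' @param x A `tf_circuit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circuit_dot <- function(x, path) {
  stopifnot(inherits(x, "tf_circuit"))
  lines <- c("digraph circuit {",
             paste0("  ", x$nodes, ";"),
             sprintf("  %s -> %s [label=\"%s/%s\"];",
                     x$edges$regulator, x$edges$target, x$edges$context,
                     x$edges$sign),
             "}")
  writeLines(lines, path)
  invisible(path)
}
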