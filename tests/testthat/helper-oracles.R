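# Brute-force oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (quadratic scans, explicit loops) and
# independent of the package's interval machinery.

iv <- function(chrom, start, end, signal = NULL, ...) {
  out <- tibble::tibble(chrom = chrom, start = start, end = end, ...)
  if (!is.null(signal)) out$signal <- signal
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 500, signal = FALSE) {
  start <- floor(runif(n, 0, max_pos - max_len))
  len <- ceiling(runif(n, 1, max_len))
  out <- tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                        start = start, end = start + len)
  if (signal) out$signal <- runif(n, 0, 50)
  dplyr::arrange(out, chrom, start, end)
}

# all-vs-all overlap scan (half-open convention)
brute_overlap_pairs <- function(a, b, min_bp = 1) {
  res <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_bp) res[[length(res) + 1]] <- c(i, j, ov)
  }
  if (!length(res)) {
    return(tibble::tibble(idx_a = integer(), idx_b = integer(),
                          overlap_bp = numeric()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(idx_a = m[, 1], idx_b = m[, 2], overlap_bp = m[, 3])
}

brute_overlaps_any <- function(a, b, min_bp = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >= min_bp)
  }, logical(1))
}

# nested-if chromatin state annotation
brute_annotate <- function(regions, sm) {
  hit <- function(r, cls) {
    nrow(cls) > 0 && any(cls$chrom == r$chrom &
                           pmin(r$end, cls$end) - pmax(r$start, cls$start) >= 1)
  }
  vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    if (hit(r, sm$promoters)) "promoter"
    else if (hit(r, sm$super_enhancers)) "super_enhancer"
    else if (hit(r, sm$typical_enhancers)) "typical_enhancer"
    else if (hit(r, sm$super_methylated)) "super_methylated"
    else if (hit(r, sm$typical_methylated)) "typical_methylated"
    else "none"
  }, character(1))
}

# exhaustive scan over candidate cutpoints: the cutpoint is the unique
# position c such that the finite-difference slope of the rescaled curve is
# <= 1 strictly before c and > 1 at c
brute_call_super <- function(signals) {
  n <- length(signals)
  s <- sort(signals)
  if (max(s) == min(s)) return(rep(FALSE, n))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  cut <- NA
  for (c in seq_len(n - 1)) {
    sl <- (y[c + 1] - y[c]) / (x[c + 1] - x[c])
    before_ok <- TRUE
    if (c > 1) {
      for (b in seq_len(c - 1)) {
        if ((y[b + 1] - y[b]) / (x[b + 1] - x[b]) > 1) before_ok <- FALSE
      }
    }
    if (sl > 1 && before_ok) { cut <- c; break }
  }
  flags_sorted <- rep(FALSE, n)
  if (!is.na(cut)) flags_sorted[(cut + 1):n] <- TRUE
  # map back: region is super iff its signal ranks above the cut position
  ord <- order(signals)
  flags <- logical(n)
  flags[ord] <- flags_sorted
  flags
}

# naive per-base binned signal mean
brute_signal_matrix <- function(track, centers, window, bin, library_size) {
  nb <- window %/% bin
  mat <- matrix(0, nrow(centers), nb)
  for (i in seq_len(nrow(centers))) {
    mid <- (centers$start[i] + centers$end[i]) %/% 2
    ws <- mid - window %/% 2
    for (b in seq_len(nb)) {
      bs <- ws + (b - 1) * bin; be <- bs + bin
      tot <- 0
      for (j in seq_len(nrow(track))) {
        if (track$chrom[j] != centers$chrom[i]) next
        ov <- min(be, track$end[j]) - max(bs, track$start[j])
        if (ov > 0) tot <- tot + ov * track$value[j]
      }
      mat[i, b] <- tot / bin
    }
  }
  mat * 1e6 / library_size
}

# exhaustive TSS scan for region-gene assignment
brute_assign <- function(regions, genes, tads) {
  res <- list()
  for (i in seq_len(nrow(regions))) {
    mid <- (regions$start[i] + regions$end[i]) %/% 2
    tid <- NA
    for (t in seq_len(nrow(tads))) {
      if (tads$chrom[t] == regions$chrom[i] && mid >= tads$start[t] &&
          mid < tads$end[t]) tid <- t
    }
    gs <- character(0)
    if (!is.na(tid)) {
      for (g in seq_len(nrow(genes))) {
        if (genes$chrom[g] == tads$chrom[tid] &&
            genes$tss[g] >= tads$start[tid] && genes$tss[g] < tads$end[tid]) {
          gs <- c(gs, genes$gene_id[g])
        }
      }
    }
    if (!length(gs)) {
      cand <- genes[genes$chrom == regions$chrom[i], ]
      if (nrow(cand)) gs <- cand$gene_id[which.min(abs(cand$tss - mid))]
    }
    for (g in gs) res[[length(res) + 1]] <- c(i, g)
  }
  if (!length(res)) {
    return(tibble::tibble(region_idx = integer(), gene_id = character()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(region_idx = as.integer(m[, 1]), gene_id = m[, 2]) |>
    dplyr::arrange(region_idx, gene_id)
}

# default simulated dataset used by several test files (built once)
default_sim <- local({
  cache <- NULL
  function(seed = 7, noise_sd = 0, ...) {
    key <- paste(seed, noise_sd, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    cfg <- sim_config(seed = seed, noise_sd = noise_sd, ...)
    gp <- simulate_genome(cfg)
    cis <- simulate_cistromes(cfg, gp)
    kd <- simulate_knockdown_counts(cfg, gp, cis$truth)
    value <- list(cfg = cfg, gp = gp, cis = cis, kd = kd)
    cache <<- list(key = key, value = value)
    value
  }
})

run_deg <- function(sim) {
  norm <- normalize_counts(sim$kd$counts, sim$kd$samples)
  call_high_confidence(log2fc_table(norm, sim$kd$samples))
}

recovery_counts <- function(sim, deg) {
  tg <- sim$kd$truth$targets
  ok_mode <- 0; ok_sign <- 0; tot <- 0
  for (ctx in c("FTSEC", "HGSC")) {
    calls <- classify_targets(deg,
                              sim$cis$tf_peaks[sim$cis$tf_peaks$context == ctx, ],
                              sim$gp$genes, sim$gp$tads, context = ctx)
    m <- dplyr::inner_join(tg[tg$context == ctx, ], calls,
                           by = c("tf", "gene_id", "context"),
                           suffix = c("_t", "_c"))
    tot <- tot + sum(tg$context == ctx)
    ok_mode <- ok_mode + sum(m$mode_t == m$mode_c)
    ok_sign <- ok_sign + sum(m$sign_t == m$sign_c)
  }
  c(mode = ok_mode, sign = ok_sign, total = tot)
}

mini_map_for_acceptance <- function() {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 5000)
  ac <- iv("chr1", c(20000, 40000, 60000), c(21000, 41000, 61000),
           signal = c(5, 4, 400))
  me <- iv("chr1", c(80000, 90000, 95000), c(81000, 91000, 96000),
           signal = c(3, 2, 100))
  build_state_map(ac, me, genes, stitch_distance = 1000)
}
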