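# Synthetic mini-genome generator with planted ground truth.
#
# Geometry is laid out on a repeating 15 kb unit so that ROSE-style stitching
# at the default 12,500 bp distance never fuses independently planted loci:
#   TE unit : one H3K27ac peak [0,1000) + 3 gene TSSs (3500/7000/10500) +
#             distal TF-binding slots
#   SE pair : two consecutive units carrying 4 high-signal H3K27ac
#             constituents (offsets 0/3500/7000/10500, 1 kb wide)
#   ME pair/units : H3K27me3 domains (2 kb), super-methylated pairs carry
#             3 high-signal domains (offsets 0/5000/10000)
# All planted TF-binding loci are >= 100 bp apart, so a gap-0 union of peak
# sets reproduces the planted loci exactly.

TFS <- c("MECOM", "PAX8", "SOX17", "WT1")
CONTEXTS <- c("FTSEC", "HGSC")
CELL_LINES <- list(FTSEC = c("FT246", "FT282"), HGSC = c("KURAMOCHI", "OVCAR4"))
CONDITIONS <- c("control_1", "control_2", "siMECOM", "siPAX8", "siSOX17", "siWT1")

UNIT_BP <- 15000
UNIT_PATTERN <- c("TE", "TE", "ME", "ME", "TE", "TE", "SE", "SE", "TE", "TE", "TE")
GENE_OFFSETS <- c(3500, 7000, 10500)
SE_CON_OFFSETS <- c(0, 3500, 7000, 10500)
ME3_SUPER_OFFSETS <- c(0, 5000, 10000)
DISTAL_OFFSETS <- rbind(
  c(1100, 1500),
  cbind(c(1900, 2500, 3900, 4500, 5100, 5700, 7400, 8000, 8600, 9200, 10900, 11500),
        c(1900, 2500, 3900, 4500, 5100, 5700, 7400, 8000, 8600, 9200, 10900, 11500) + 500),
  cbind(c(12600, 13200, 13800, 14400), c(12600, 13200, 13800, 14400) + 500)
)
COBIND_K_PROB <- c(0.2, 0.2, 0.2, 0.4)
# secondary promoter-window slots (per gene slot offset) used when binding
# must cover both contexts without any shared (common) locus
ALT_PROM_OFFSETS <- list(`3500` = c(1600, 1850), `7000` = c(6300, 6600),
                         `10500` = c(9800, 10100))

set_sim_seed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' seconds-scale mini-genome: 2 chromosomes of 1 Mb, 200 genes, 20 TADs,
#' roughly 500 binding sites per factor and context, and 92 spike-in rows
#' (the size of the ERCC set).
#'
#' @param seed Integer seed; all generator functions are deterministic given
#'   it (Mersenne-Twister, inversion normals).
#' @param n_chroms,chrom_length Genome size.
#' @param n_genes Number of gene models.
#' @param n_tads Number of topologically associated domains (tile the genome).
#' @param peaks_per_tf Approximate number of binding sites per TF and context.
#' @param fraction_context_specific Fraction of planted loci (TF binding and
#'   enhancer units) active in only one of the two cellular contexts.
#' @param n_spikeins Number of exogenous spike-in rows in count matrices.
#' @param deg_effect_log2fc Magnitude of planted knockdown effects (log2).
#' @param noise_sd Log2-scale count noise standard deviation.
#' @param n_samples_per_condition Replicates per siRNA/control condition.
#' @param global_shift Log2 library-composition distortion applied to the
#'   gene (non-spike-in) rows of every knockdown sample; spike-ins are drawn
#'   identically across samples regardless.
#' @param n_se_loci Number of planted super-enhancer loci across contexts.
#' @param n_tissues,samples_per_tissue Size of the simulated tissue panel.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 7, n_chroms = 2, chrom_length = 1e6,
                       n_genes = 200, n_tads = 20, peaks_per_tf = 500,
                       fraction_context_specific = 0.5, n_spikeins = 92,
                       deg_effect_log2fc = 2, noise_sd = 0.1,
                       n_samples_per_condition = 4, global_shift = 0,
                       n_se_loci = 12, n_tissues = 21, samples_per_tissue = 20) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_tads = as.integer(n_tads),
              peaks_per_tf = as.integer(peaks_per_tf),
              fraction_context_specific = fraction_context_specific,
              n_spikeins = as.integer(n_spikeins),
              deg_effect_log2fc = deg_effect_log2fc, noise_sd = noise_sd,
              n_samples_per_condition = as.integer(n_samples_per_condition),
              global_shift = global_shift, n_se_loci = as.integer(n_se_loci),
              n_tissues = as.integer(n_tissues),
              samples_per_tissue = as.integer(samples_per_tissue),
              rng = "Mersenne-Twister/Inversion/Rejection")
  counts <- c("n_chroms", "chrom_length", "n_genes", "n_tads", "peaks_per_tf",
              "n_spikeins", "n_samples_per_condition", "n_se_loci",
              "n_tissues", "samples_per_tissue")
  if (any(unlist(cfg[counts]) < 1)) stop("all size parameters must be >= 1")
  if (cfg$fraction_context_specific < 0 || cfg$fraction_context_specific > 1) {
    stop("fraction_context_specific must lie in [0, 1]")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  structure(cfg, class = "sim_config")
}

# role layout of 15 kb units along each chromosome
unit_table <- function(config) {
  n_units <- config$chrom_length %/% UNIT_BP
  if (n_units < length(UNIT_PATTERN)) {
    stop("chromosome too short for the unit layout (needs >= ",
         length(UNIT_PATTERN) * UNIT_BP, " bp)")
  }
  roles <- rep_len(UNIT_PATTERN, n_units)
  purrr::map_dfr(seq_len(config$n_chroms), function(ci) {
    tibble::tibble(chrom = paste0("chr", ci),
                   unit = seq_len(n_units),
                   start = (seq_len(n_units) - 1) * UNIT_BP,
                   role = roles)
  })
}

# SE and super-ME loci occupy the first unit of each adjacent same-role pair
pair_first <- function(units, which_role) {
  units |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(.pair_ok = .data$role == .env$which_role &
                    dplyr::lead(.data$role, default = "") == .env$which_role &
                    dplyr::lag(.data$role, default = "") != .env$which_role) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.pair_ok) |>
    dplyr::select(-".pair_ok")
}

#' Simulate the mini-genome: layout, gene models and TADs
#'
#' TADs tile each chromosome without overlap and every gene TSS falls inside
#' exactly one TAD. Four genes are designated as the master-TF loci
#' (MECOM, PAX8, SOX17, WT1) and four TADs are reserved as per-factor
#' exclusion domains (used downstream to plant indirect targets).
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (layout tibble), `genes` (gene models:
#'   gene_id, chrom, strand, tss, length, tad_id), `tads`, and internal
#'   `units`/`tf_tads` used by [simulate_cistromes()].
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_tads < config$n_chroms) stop("n_tads must be >= n_chroms")
  set_sim_seed(config$seed)
  genome <- genome_layout(paste0("chr", seq_len(config$n_chroms)),
                          rep(config$chrom_length, config$n_chroms))
  # tads: near-even split across chromosomes, tiling each chromosome
  per_chrom <- rep(config$n_tads %/% config$n_chroms, config$n_chroms)
  extra <- config$n_tads %% config$n_chroms
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1
  tads <- purrr::map_dfr(seq_len(config$n_chroms), function(ci) {
    k <- per_chrom[ci]
    bounds <- round(seq(0, config$chrom_length, length.out = k + 1))
    tibble::tibble(chrom = paste0("chr", ci),
                   start = bounds[-(k + 1)], end = bounds[-1])
  })
  tads$tad_id <- sprintf("tad_%02d", seq_len(nrow(tads)))

  units <- unit_table(config)
  # gene slots live in TE units
  slots <- units |>
    dplyr::filter(.data$role == "TE") |>
    tidyr::crossing(offset = GENE_OFFSETS) |>
    dplyr::mutate(tss = .data$start + .data$offset) |>
    dplyr::arrange(.data$chrom, .data$tss)
  slots$tad_id <- locate_tad(slots$chrom, slots$tss, tads)
  if (nrow(slots) < config$n_genes) {
    stop("genome too small for n_genes gene slots; enlarge chrom_length")
  }
  # per-TF exclusion TADs (planted indirect targets live there); keep every
  # gene slot inside them so each holds enough genes
  excl_ids <- tads$tad_id[unique(round(seq(2, max(2, nrow(tads) - 1),
                                           length.out = min(4, nrow(tads)))))]
  excl_ids <- rep_len(excl_ids, 4)
  tf_tads <- tibble::tibble(tf = TFS, tad_id = excl_ids)
  keep <- which(slots$tad_id %in% excl_ids)
  pool <- setdiff(seq_len(nrow(slots)), keep)
  n_more <- config$n_genes - length(keep)
  if (n_more < 0) stop("n_genes smaller than exclusion-TAD gene slots")
  keep <- sort(c(keep, sample(pool, n_more)))
  genes <- slots[keep, c("chrom", "tss", "tad_id")]
  genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))
  genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
  genes$length <- sample(500:5000, nrow(genes), replace = TRUE)
  # designate the four TF genes in distinct non-exclusion TADs
  cand <- genes |>
    dplyr::filter(!.data$tad_id %in% excl_ids) |>
    dplyr::group_by(.data$tad_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  if (nrow(cand) < 4) stop("not enough TADs to place the four TF genes")
  tf_rows <- sample(nrow(cand), 4)
  genes$gene_id[match(paste(cand$chrom, cand$tss)[tf_rows],
                      paste(genes$chrom, genes$tss))] <- TFS
  genes <- genes[, c("gene_id", "chrom", "strand", "tss", "length", "tad_id")]
  list(genome = genome, genes = genes, tads = tads, units = units,
       tf_tads = tf_tads)
}

# tad id containing each position (tads tile, so containment is unique)
locate_tad <- function(chrom, pos, tads) {
  out <- rep(NA_character_, length(pos))
  for (cc in unique(chrom)) {
    tt <- tads[tads$chrom == cc, ]
    i <- chrom == cc
    idx <- findInterval(pos[i], tt$start)
    ok <- idx >= 1 & pos[i] < c(tt$end, Inf)[pmax(idx, 1)]
    out[i][ok] <- tt$tad_id[idx[ok]]
  }
  out
}

context_of <- function(status) {
  if (status == "common") CONTEXTS else status
}

draw_status <- function(n, f) {
  spec <- stats::runif(n) < f
  st <- rep("common", n)
  st[spec] <- sample(CONTEXTS, sum(spec), replace = TRUE)
  st
}

#' Simulate per-context cistromes, histone landscapes and planted truth
#'
#' Plants (i) shared and context-specific co-bound loci for the four master
#' TFs, (ii) a hockey-stick H3K27ac signal distribution (a handful of
#' super-enhancer loci carry a disproportionate share of signal), (iii)
#' H3K27me3 domains disjoint from active enhancers with their own
#' super-methylated tail, and (iv) geometrically consistent direct /
#' putative / indirect target genes plus a signed core-regulatory circuit.
#'
#' @param config A [sim_config()].
#' @param gp Output of [simulate_genome()] under the same config.
#' @return A list: `tf_peaks` (long tibble: context, tf, chrom, start, end,
#'   locus_id), `h3k27ac` / `h3k27me3` (long signal-peak tibbles with a
#'   `context` column), and `truth` (a `tfrewire_truth` object).
#' @export
simulate_cistromes <- function(config, gp) {
  stopifnot(inherits(config, "sim_config"))
  set_sim_seed(config$seed + 1L)
  f <- config$fraction_context_specific
  units <- gp$units
  genes <- gp$genes
  tads <- gp$tads

  ## ---- histone landscapes -------------------------------------------------
  se_first <- pair_first(units, "SE")
  if (nrow(se_first) < 1) stop("no super-enhancer unit pairs fit this genome")
  n_se <- min(config$n_se_loci, nrow(se_first))
  se_loci <- se_first[sample(nrow(se_first), n_se), ]
  n_spec_se <- round(f * n_se)
  se_status <- sample(c(rep("common", n_se - n_spec_se),
                        rep(CONTEXTS, length.out = n_spec_se)))
  se_loci$status <- se_status
  se_loci$se_id <- sprintf("se_%02d", seq_len(n_se))

  te_units <- dplyr::filter(units, .data$role == "TE")
  te_units$status <- draw_status(nrow(te_units), f)
  te_units$signal <- stats::runif(nrow(te_units), 1, 20)

  me_first <- pair_first(units, "ME")
  n_sme <- min(4L, nrow(me_first))
  sme_loci <- me_first[sample(nrow(me_first), n_sme), ]
  me_units <- units |>
    dplyr::filter(.data$role == "ME") |>
    dplyr::anti_join(
      tidyr::crossing(sme_loci[, c("chrom", "unit")] |>
                        dplyr::rename(u0 = "unit"), d = c(0L, 1L)) |>
        dplyr::transmute(chrom = .data$chrom, unit = .data$u0 + .data$d),
      by = c("chrom", "unit"))
  me_units$signal <- stats::runif(nrow(me_units), 1, 20)

  se_con <- tidyr::crossing(se_loci[, c("chrom", "start", "status", "se_id")],
                            off = SE_CON_OFFSETS) |>
    dplyr::mutate(pstart = .data$start + .data$off,
                  pend = .data$pstart + 1000,
                  signal = stats::runif(dplyr::n(), 200, 300))

  h3k27ac <- purrr::map_dfr(CONTEXTS, function(ctx) {
    te <- te_units[te_units$status %in% c("common", ctx), ]
    con <- se_con[se_con$status %in% c("common", ctx), ]
    dplyr::bind_rows(
      tibble::tibble(context = ctx, chrom = te$chrom, start = te$start,
                     end = te$start + 1000, signal = te$signal),
      tibble::tibble(context = ctx, chrom = con$chrom, start = con$pstart,
                     end = con$pend, signal = con$signal)
    ) |> dplyr::arrange(.data$chrom, .data$start)
  })

  sme_con <- tidyr::crossing(sme_loci[, c("chrom", "start")],
                             off = ME3_SUPER_OFFSETS) |>
    dplyr::mutate(pstart = .data$start + .data$off, pend = .data$pstart + 2000,
                  signal = stats::runif(dplyr::n(), 200, 300))
  h3k27me3 <- purrr::map_dfr(CONTEXTS, function(ctx) {
    dplyr::bind_rows(
      tibble::tibble(context = ctx, chrom = me_units$chrom,
                     start = me_units$start, end = me_units$start + 2000,
                     signal = me_units$signal),
      tibble::tibble(context = ctx, chrom = sme_con$chrom,
                     start = sme_con$pstart, end = sme_con$pend,
                     signal = sme_con$signal)
    ) |> dplyr::arrange(.data$chrom, .data$start)
  })

  planted_se <- purrr::map_dfr(CONTEXTS, function(ctx) {
    act <- se_loci[se_loci$status %in% c("common", ctx), ]
    tibble::tibble(context = ctx, se_id = act$se_id, chrom = act$chrom,
                   start = act$start,
                   end = act$start + max(SE_CON_OFFSETS) + 1000)
  })
  planted_sme <- purrr::map_dfr(CONTEXTS, function(ctx) {
    tibble::tibble(context = ctx, chrom = sme_loci$chrom,
                   start = sme_loci$start,
                   end = sme_loci$start + max(ME3_SUPER_OFFSETS) + 2000)
  })

  ## ---- candidate TF-binding loci ------------------------------------------
  prom_cand <- tibble::tibble(kind = "prom", gene_id = genes$gene_id,
                              chrom = genes$chrom,
                              start = pmax(genes$tss - 300, 0),
                              end = genes$tss + 300)
  enh_cand <- tibble::tibble(kind = "enh", gene_id = NA_character_,
                             chrom = te_units$chrom,
                             start = te_units$start + 200,
                             end = te_units$start + 800)
  secon_cand <- tibble::tibble(kind = "se_con", gene_id = NA_character_,
                               chrom = se_con$chrom,
                               start = se_con$pstart + 200,
                               end = se_con$pstart + 800)
  distal_cand <- tidyr::crossing(te_units[, c("chrom", "start")] |>
                                   dplyr::rename(ustart = "start"),
                                 i = seq_len(nrow(DISTAL_OFFSETS))) |>
    dplyr::transmute(kind = "distal", gene_id = NA_character_,
                     chrom = .data$chrom,
                     start = .data$ustart + DISTAL_OFFSETS[.data$i, 1],
                     end = .data$ustart + DISTAL_OFFSETS[.data$i, 2])
  me3_cand <- tibble::tibble(kind = "me3", gene_id = NA_character_,
                             chrom = me_units$chrom,
                             start = me_units$start + 600,
                             end = me_units$start + 1200)
  cand <- dplyr::bind_rows(prom_cand, enh_cand, secon_cand, distal_cand, me3_cand)
  cand$tad_id <- locate_tad(cand$chrom, (cand$start + cand$end) %/% 2, tads)

  ## ---- planted targets ----------------------------------------------------
  effect <- config$deg_effect_log2fc
  excl <- gp$tf_tads
  # planted genes keep their whole +/-2 kb promoter window inside their TAD,
  # so promoter evidence can never leak across a TAD boundary
  bounds <- tads[match(genes$tad_id, tads$tad_id), ]
  interior <- genes$tss - 2000 >= bounds$start & genes$tss + 2000 <= bounds$end
  pool <- genes |>
    dplyr::filter(interior, !.data$gene_id %in% TFS,
                  !.data$tad_id %in% excl$tad_id)
  pool_ids <- sample(pool$gene_id)   # shuffled; consumed without replacement
  take <- function(n) {
    if (length(pool_ids) < n) stop("gene pool exhausted; increase n_genes")
    out <- pool_ids[seq_len(n)]
    pool_ids <<- pool_ids[-seq_len(n)]
    out
  }
  ctx_plan <- c("FTSEC", "FTSEC", "FTSEC", "HGSC", "HGSC", "HGSC", "both", "both")
  planted <- purrr::map_dfr(TFS, function(tf) {
    direct <- tibble::tibble(tf = tf, gene_id = take(8), mode = "direct",
                             ctxs = ctx_plan)
    putative <- tibble::tibble(tf = tf, gene_id = take(8), mode = "putative",
                               ctxs = ctx_plan)
    epool <- genes$gene_id[interior &
                             genes$tad_id == excl$tad_id[excl$tf == tf] &
                             !genes$gene_id %in% TFS]
    epick <- sample(epool, 6)
    indirect <- tibble::tibble(tf = tf, gene_id = epick, mode = "indirect",
                               ctxs = c("FTSEC", "FTSEC", "HGSC", "HGSC",
                                        "both", "both"))
    dplyr::bind_rows(direct, putative, indirect)
  })
  planted <- planted |>
    tidyr::uncount(ifelse(planted$ctxs == "both", 2, 1), .id = "dup") |>
    dplyr::mutate(context = ifelse(.data$ctxs == "both",
                                   CONTEXTS[.data$dup], .data$ctxs)) |>
    dplyr::select("tf", "gene_id", "context", "mode", ctx_span = "ctxs")
  planted$sign <- sample(c("up", "down"), nrow(planted), replace = TRUE)
  # a planted gene keeps one sign per (tf, gene) across contexts
  planted <- planted |>
    dplyr::group_by(.data$tf, .data$gene_id) |>
    dplyr::mutate(sign = .data$sign[1]) |>
    dplyr::ungroup()

  # core-regulatory circuit among the four TF genes (direct by construction)
  circuit <- dplyr::bind_rows(
    tidyr::crossing(regulator = "PAX8", target = c("MECOM", "SOX17", "WT1"),
                    context = CONTEXTS, sign = "down"),
    tidyr::crossing(regulator = "WT1", target = c("MECOM", "PAX8", "SOX17"),
                    context = CONTEXTS, sign = "down"),
    tidyr::crossing(regulator = "SOX17", target = c("MECOM", "WT1"),
                    context = CONTEXTS, sign = "down"),
    tibble::tibble(regulator = "SOX17", target = "PAX8", context = "HGSC",
                   sign = "up"),
    tidyr::crossing(regulator = "MECOM", target = c("SOX17", "WT1"),
                    context = "HGSC", sign = "up"),
    tidyr::crossing(regulator = TFS, context = CONTEXTS) |>
      dplyr::mutate(target = .data$regulator, sign = "down")
  )
  planted <- dplyr::bind_rows(
    planted,
    circuit |>
      dplyr::transmute(tf = .data$regulator, gene_id = .data$target,
                       context = .data$context, mode = "direct",
                       ctx_span = "circuit", sign = .data$sign))
  planted$effect_log2fc <- ifelse(planted$sign == "up", effect, -effect)

  ## ---- select loci and assign membership ----------------------------------
  p_mem <- sum(COBIND_K_PROB * (1:4)) / 4
  p_act <- (1 - f) + f / 2
  n_need <- ceiling(config$peaks_per_tf / (p_mem * p_act))
  # forced loci: every enhancer/constituent locus, promoter loci of planted
  # direct genes + the four TF genes, one putative-evidence distal per
  # planted putative target
  forced_prom_genes <- unique(c(TFS, planted$gene_id[planted$mode == "direct"]))
  forced_prom <- which(cand$kind == "prom" & cand$gene_id %in% forced_prom_genes)
  forced_base <- c(which(cand$kind %in% c("enh", "se_con")), forced_prom)

  f1 <- f >= 1   # no locus may be shared between contexts
  put <- planted |>
    dplyr::filter(.data$mode == "putative") |>
    dplyr::group_by(.data$tf, .data$gene_id) |>
    dplyr::summarise(both = dplyr::n() == 2, ctx = .data$context[1],
                     .groups = "drop")
  put <- dplyr::left_join(put, genes, by = "gene_id")
  # the evidence peak must clear the +/-2 kb promoter window of every
  # same-factor putative gene, or the later promoter scrub would erase it
  ev_slots <- lapply(seq_len(nrow(put)), function(i) {
    same_tf <- put[put$tf == put$tf[i], ]
    ok <- which(cand$kind == "distal" & cand$tad_id == put$tad_id[i])
    if (length(ok)) {
      clear <- vapply(ok, function(j) {
        all(cand$chrom[j] != same_tf$chrom |
              cand$end[j] <= same_tf$tss - 2000 |
              cand$start[j] >= same_tf$tss + 2000)
      }, logical(1))
      ok <- ok[clear]
    }
    n_want <- if (put$both[i] && f1) 2L else 1L
    if (length(ok) < n_want) {
      stop("no putative evidence slot in TAD ", put$tad_id[i])
    }
    rot <- 1 + (i %% length(ok))
    unique(c(ok[rot], ok[-rot]))[seq_len(n_want)]
  })
  put$evidence_idx <- vapply(ev_slots, `[`, integer(1), 1)
  put$evidence_idx2 <- vapply(ev_slots, function(x) {
    if (length(x) > 1) x[2] else NA_integer_
  }, integer(1))
  forced <- unique(c(forced_base, put$evidence_idx,
                     put$evidence_idx2[!is.na(put$evidence_idx2)]))

  rest <- setdiff(seq_len(nrow(cand)), forced)
  n_fill <- n_need - length(forced)
  if (n_fill > length(rest)) {
    stop("peaks_per_tf exceeds genome capacity without overlap; ",
         "reduce peaks_per_tf or enlarge the genome")
  }
  loci <- cand[sort(c(forced, sample(rest, max(n_fill, 0)))), ]
  loci$locus_id <- sprintf("locus_%04d", seq_len(nrow(loci)))
  loci$status <- draw_status(nrow(loci), f)
  k <- sample(1:4, nrow(loci), replace = TRUE, prob = COBIND_K_PROB)
  memb <- matrix(FALSE, nrow(loci), 4, dimnames = list(NULL, TFS))
  for (i in seq_len(nrow(loci))) memb[i, sample(4, k[i])] <- TRUE

  # secondary context-specific promoter-window loci, appended at the end;
  # needed when binding must cover both contexts but no common loci exist
  alt_rows <- list()
  add_alt <- function(gene_id, tf) {
    g <- genes[genes$gene_id == gene_id, ]
    off <- as.character(g$tss %% UNIT_BP)
    a <- ALT_PROM_OFFSETS[[off]]
    if (is.null(a)) stop("no alternate promoter slot for gene ", gene_id)
    cur <- alt_rows[[gene_id]]
    if (is.null(cur)) {
      cur <- list(chrom = g$chrom, start = g$tss - as.numeric(off) + a[1],
                  end = g$tss - as.numeric(off) + a[2],
                  tad_id = g$tad_id,
                  tfs = stats::setNames(rep(FALSE, 4), TFS))
    }
    cur$tfs[tf] <- TRUE
    alt_rows[[gene_id]] <<- cur
  }
  # TF-gene promoters: bound by all four factors in both contexts
  tfg <- which(loci$kind == "prom" & loci$gene_id %in% TFS)
  memb[tfg, ] <- TRUE
  if (f1) {
    loci$status[tfg] <- "FTSEC"
    for (g in loci$gene_id[tfg]) for (tf in TFS) add_alt(g, tf)
  } else {
    loci$status[tfg] <- "common"
  }
  # planted direct: the TF binds the gene promoter in the planted context(s)
  dx <- planted |>
    dplyr::filter(.data$mode == "direct", !.data$gene_id %in% TFS) |>
    dplyr::group_by(.data$tf, .data$gene_id) |>
    dplyr::summarise(both = dplyr::n() == 2, ctx = .data$context[1],
                     .groups = "drop")
  for (i in seq_len(nrow(dx))) {
    idx <- which(loci$kind == "prom" & loci$gene_id == dx$gene_id[i])
    memb[idx, dx$tf[i]] <- TRUE
    if (dx$both[i]) {
      if (f1) {
        loci$status[idx] <- "FTSEC"
        add_alt(dx$gene_id[i], dx$tf[i])
      } else {
        loci$status[idx] <- "common"
      }
    } else if (loci$status[idx] != "common") loci$status[idx] <- dx$ctx[i]
  }
  # planted putative: evidence distal bound; scrub the TF from the gene's
  # promoter neighbourhood so direct can never pre-empt it
  for (i in seq_len(nrow(put))) {
    # evidence_idx indexes cand; map to the selected loci by coordinates
    ev <- cand[put$evidence_idx[i], ]
    idx <- which(loci$chrom == ev$chrom & loci$start == ev$start)
    memb[idx, put$tf[i]] <- TRUE
    if (put$both[i]) {
      if (f1) {
        loci$status[idx] <- "FTSEC"
        ev2 <- cand[put$evidence_idx2[i], ]
        idx2 <- which(loci$chrom == ev2$chrom & loci$start == ev2$start)
        memb[idx2, put$tf[i]] <- TRUE
        loci$status[idx2] <- "HGSC"
      } else {
        loci$status[idx] <- "common"
      }
    } else if (loci$status[idx] != "common") loci$status[idx] <- put$ctx[i]
    near <- which(loci$chrom == put$chrom[i] &
                    loci$start < put$tss[i] + 2000 &
                    loci$end > put$tss[i] - 2000)
    memb[near, put$tf[i]] <- FALSE
  }
  # exclusion TADs: the matching TF never binds there (indirect by geometry)
  for (i in seq_len(nrow(excl))) {
    memb[loci$tad_id %in% excl$tad_id[i], excl$tf[i]] <- FALSE
  }
  # no locus may end up unbound
  none <- which(rowSums(memb) == 0)
  for (i in none) {
    allowed <- TFS[!TFS %in% excl$tf[excl$tad_id == loci$tad_id[i]]]
    bad_tf <- put$tf[put$chrom == loci$chrom[i] &
                       put$tss + 2000 > loci$start[i] &
                       put$tss - 2000 < loci$end[i]]
    allowed <- setdiff(allowed, bad_tf)
    if (length(allowed)) memb[i, sample(allowed, 1)] <- TRUE
  }
  keep <- rowSums(memb) > 0
  loci <- loci[keep, , drop = FALSE]
  memb <- memb[keep, , drop = FALSE]
  if (length(alt_rows)) {
    alt <- tibble::tibble(
      kind = "prom_alt", gene_id = names(alt_rows),
      chrom = vapply(alt_rows, function(x) x$chrom, character(1)),
      start = vapply(alt_rows, function(x) x$start, numeric(1)),
      end = vapply(alt_rows, function(x) x$end, numeric(1)),
      tad_id = vapply(alt_rows, function(x) x$tad_id, character(1)),
      status = "HGSC")
    loci <- dplyr::bind_rows(loci, alt)
    memb <- rbind(memb, t(vapply(alt_rows, function(x) x$tfs, logical(4))))
  }
  loci$locus_id <- sprintf("locus_%04d", seq_len(nrow(loci)))

  cobinding <- dplyr::bind_cols(
    loci[, c("locus_id", "chrom", "start", "end", "kind", "status", "tad_id")],
    tibble::as_tibble(memb))

  tf_peaks <- purrr::map_dfr(CONTEXTS, function(ctx) {
    act <- loci$status %in% c("common", ctx)
    purrr::map_dfr(TFS, function(tf) {
      sel <- act & memb[, tf]
      tibble::tibble(context = ctx, tf = tf, chrom = loci$chrom[sel],
                     start = loci$start[sel], end = loci$end[sel],
                     locus_id = loci$locus_id[sel])
    })
  }) |> dplyr::arrange(.data$context, .data$tf, .data$chrom, .data$start)

  truth <- structure(list(
    superenhancers = planted_se,
    supermethylated = planted_sme,
    cobinding = cobinding,
    targets = planted[, c("tf", "gene_id", "context", "mode", "sign",
                          "effect_log2fc")],
    circuit = circuit,
    tf_tads = excl,
    global_shift = config$global_shift,
    config = unclass(config)
  ), class = "tfrewire_truth")

  list(tf_peaks = tf_peaks, h3k27ac = h3k27ac, h3k27me3 = h3k27me3,
       truth = truth)
}

#' Extract one context/factor peak set from a long peak tibble
#'
#' @param peaks Long tibble as returned in `simulate_cistromes()$tf_peaks`
#'   or `$h3k27ac` (any tibble with `context` and optionally `tf`).
#' @param context Cellular context label.
#' @param tf Optional factor name.
#' @return An interval tibble.
#' @export
peaks_for <- function(peaks, context, tf = NULL) {
  out <- dplyr::filter(peaks, .data$context == !!context)
  if (!is.null(tf)) out <- dplyr::filter(out, .data$tf == !!tf)
  as_intervals(dplyr::select(out, -dplyr::any_of(c("context", "tf"))))
}

#' Simulate knockdown RNA-seq count matrices with spike-ins
#'
#' Baseline counts are log-normal. Planted targets are shifted by their
#' planted effect in the matching TF-knockdown samples of both cell lines of
#' their context. Spike-in rows are drawn identically across all samples;
#' gene rows of every knockdown (non-control) sample are then multiplied by
#' `2^global_shift` to emulate library-composition distortion that only the
#' spike-ins can certify. Counts are rounded to integers.
#'
#' @param config A [sim_config()].
#' @param gp Output of [simulate_genome()].
#' @param truth `tfrewire_truth` from [simulate_cistromes()].
#' @return A list: `counts` (tibble: gene_id, length, is_spikein, one column
#'   per sample), `samples` (sample metadata: sample, cell_line, context,
#'   condition, replicate), and `truth` with `expected_log2fc` filled in
#'   (planted effect plus global shift).
#' @export
simulate_knockdown_counts <- function(config, gp, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "tfrewire_truth"))
  if (config$n_samples_per_condition < 1) {
    stop("n_samples_per_condition must be >= 1")
  }
  set_sim_seed(config$seed + 2L)
  genes <- gp$genes
  samples <- purrr::map_dfr(CONTEXTS, function(ctx) {
    tidyr::crossing(cell_line = CELL_LINES[[ctx]], condition = CONDITIONS,
                    replicate = seq_len(config$n_samples_per_condition)) |>
      dplyr::mutate(context = ctx)
  }) |>
    dplyr::mutate(sample = paste(.data$cell_line, .data$condition,
                                 paste0("r", .data$replicate), sep = "_")) |>
    dplyr::select("sample", "cell_line", "context", "condition", "replicate")

  n_g <- nrow(genes)
  n_s <- config$n_spikeins
  base_g <- stats::runif(n_g, 6, 12)
  base_s <- stats::runif(n_s, 4, 12)
  spike <- tibble::tibble(gene_id = sprintf("ERCC-%05d", seq_len(n_s)),
                          length = sample(250:2000, n_s, replace = TRUE),
                          is_spikein = TRUE)
  meta <- dplyr::bind_rows(
    tibble::tibble(gene_id = genes$gene_id, length = genes$length,
                   is_spikein = FALSE),
    spike)

  tg <- truth$targets
  mat <- matrix(0, n_g + n_s, nrow(samples),
                dimnames = list(meta$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu_g <- base_g
    cond <- samples$condition[j]
    if (startsWith(cond, "si")) {
      tf <- sub("^si", "", cond)
      hit <- tg$tf == tf & tg$context == samples$context[j]
      idx <- match(tg$gene_id[hit], genes$gene_id)
      mu_g[idx] <- mu_g[idx] + tg$effect_log2fc[hit]
      mu_g <- mu_g + config$global_shift
    }
    mu <- c(mu_g, base_s)
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(n_g + n_s, 0, config$noise_sd)
    } else 0
    mat[, j] <- round(2^(mu + noise))
  }
  truth$targets$expected_log2fc <-
    truth$targets$effect_log2fc + config$global_shift
  counts <- dplyr::bind_cols(meta, tibble::as_tibble(mat))
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate a tissue expression panel and an IHC positivity table
#'
#' Emulates a pan-normal expression survey: five planted tissue archetypes
#' over the four TFs (all-high, MECOM-high, MECOM+PAX8-high, SOX17-high,
#' all-low) with the fallopian-tube tissue carrying a shared latent factor
#' so its pairwise TF correlations dominate, plus a positivity-rate table
#' across tumor histotypes.
#'
#' @param config A [sim_config()].
#' @return A list: `expression` (sample, tissue, 4 TF columns on the
#'   log2(TPM+1) scale), `positivity` (sample, histotype, 4 rate columns),
#'   and `clusters` (planted tissue -> archetype).
#' @export
simulate_tissue_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_sim_seed(config$seed + 3L)
  n_t <- max(config$n_tissues, 6)
  tissues <- c("fallopian_tube", "uterus",
               sprintf("tissue_%02d", seq_len(n_t - 2)))
  arche <- c("MTF_high", "MTF_high",
             rep(c("M_high", "MP_high", "S_high"),
                 length.out = min(7, n_t - 2)),
             rep("MTF_low", max(0, n_t - 9)))
  profiles <- list(MTF_high = c(8, 8, 8, 8), M_high = c(8, 2, 2, 2),
                   MP_high = c(8, 8, 2, 2), S_high = c(2, 2, 8, 2),
                   MTF_low = c(2, 2, 2, 2))
  loading <- ifelse(tissues == "fallopian_tube", 1,
                    ifelse(tissues == "uterus", 0.4, 0))
  expr <- purrr::map_dfr(seq_along(tissues), function(i) {
    n <- config$samples_per_tissue
    latent <- stats::rnorm(n)
    vals <- t(vapply(seq_len(n), function(s) {
      profiles[[arche[i]]] + loading[i] * latent[s] + stats::rnorm(4, 0, 0.4)
    }, numeric(4)))
    colnames(vals) <- TFS
    dplyr::bind_cols(
      tibble::tibble(sample = paste0(tissues[i], "_s", seq_len(n)),
                     tissue = tissues[i]),
      tibble::as_tibble(vals))
  })

  histo <- tibble::tibble(
    histotype = c("HGSC", "fallopian_tube", "clear_cell", "endometrioid",
                  "mucinous", "ovary"),
    n = c(150, 12, 28, 18, 9, 25),
    mecom = c(0.6, 0.4, 0.5, 0.5, 0.15, 0.05),
    pax8 = c(0.7, 0.6, 0.6, 0.6, 0.2, 0.05),
    sox17 = c(0.7, 0.5, 0.5, 0.6, 0.15, 0.05),
    wt1 = c(0.68, 0.19, 0.05, 0.08, 0.05, 0.05))
  positivity <- purrr::map_dfr(seq_len(nrow(histo)), function(i) {
    n <- histo$n[i]
    draw <- function(m) {
      stats::rbeta(n, shape1 = pmax(m, 0.02) * 8, shape2 = pmax(1 - m, 0.02) * 8)
    }
    tibble::tibble(sample = paste0(histo$histotype[i], "_s", seq_len(n)),
                   histotype = histo$histotype[i],
                   MECOM = draw(histo$mecom[i]), PAX8 = draw(histo$pax8[i]),
                   SOX17 = draw(histo$sox17[i]), WT1 = draw(histo$wt1[i]))
  })
  list(expression = expr, positivity = positivity,
       clusters = tibble::tibble(tissue = tissues, archetype = arche))
}

#' Write planted truth to a machine-readable JSON file
#'
#' @param truth A `tfrewire_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "tfrewire_truth"))
  jsonlite::write_json(unclass(truth), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read planted truth back from JSON
#'
#' @param path Path written by [write_truth()].
#' @return A `tfrewire_truth` object with tibble components.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  tabs <- c("superenhancers", "supermethylated", "cobinding", "targets",
            "circuit", "tf_tads")
  for (nm in tabs) raw[[nm]] <- tibble::as_tibble(raw[[nm]])
  structure(raw, class = "tfrewire_truth")
}
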