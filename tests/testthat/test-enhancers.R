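# Stitching, hockey-stick super-enhancer calling, state maps, gene
# assignment and loop anchoring.

test_that("stitch fuses peaks within distance and conserves constituents", {
  pk <- iv("chr1", c(0, 5000), c(1000, 6000), signal = c(2, 3))
  one <- stitch(pk, stitch_distance = 12500)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_constituents, 2)
  expect_equal(one$total_signal, 5)

  zero <- stitch(pk, stitch_distance = 0)
  expect_equal(nrow(zero), 2)
  expect_error(stitch(pk, stitch_distance = -5), ">= 0")

  # TSS exclusion removes peaks fully inside the window before stitching
  genes <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 500)
  ex <- stitch(pk, stitch_distance = 12500, genes = genes, tss_window = 2500)
  expect_equal(sum(ex$n_constituents), 1)

  set.seed(21)
  r <- random_intervals(150, signal = TRUE)
  st <- stitch(r, stitch_distance = 400)
  expect_equal(sum(st$n_constituents), nrow(r))
  cons <- dplyr::bind_rows(st$constituents)
  expect_setequal(paste(cons$chrom, cons$start, cons$end),
                  paste(r$chrom, r$start, r$end))
  expect_equal(sum(st$total_signal), sum(r$signal))
})

test_that("call_super matches the exhaustive tangent-search oracle", {
  one_big <- call_super(tibble::tibble(total_signal = c(1, 1, 1, 1, 100)))
  expect_equal(one_big$n_super, 1)
  expect_true(one_big$regions$is_super[one_big$regions$total_signal == 100])

  linear <- call_super(tibble::tibble(total_signal = 1:50))
  expect_equal(linear$n_super, 0)

  expect_warning(zero <- call_super(tibble::tibble(total_signal = rep(0, 5))),
                 "all-zero")
  expect_equal(zero$n_super, 0)

  set.seed(31)
  for (rep in 1:50) {
    n <- sample(20:200, 1)
    n_big <- sample(1:8, 1)
    sig <- c(runif(n - n_big, 1, 20), runif(n_big, 300, 600))
    sig <- sample(sig)
    got <- call_super(tibble::tibble(total_signal = sig))
    expect_equal(got$regions$is_super, brute_call_super(sig))
  }
})

test_that("call_super is scale-invariant and monotone", {
  set.seed(32)
  sig <- c(runif(60, 1, 20), runif(5, 300, 500))
  base <- call_super(tibble::tibble(total_signal = sig))$regions$is_super
  for (mult in runif(20, 0.001, 1000)) {
    expect_equal(call_super(tibble::tibble(total_signal = sig * mult))$regions$is_super,
                 base)
  }
  # raising one region's signal never demotes it
  idx <- which(base)[1]
  sig2 <- sig
  sig2[idx] <- sig2[idx] * 3
  expect_true(call_super(tibble::tibble(total_signal = sig2))$regions$is_super[idx])
})

test_that("planted super-enhancers and super-methylated domains are recovered exactly", {
  sim <- default_sim()
  for (ctx in c("FTSEC", "HGSC")) {
    sc <- call_super(stitch(peaks_for(sim$cis$h3k27ac, ctx),
                            genes = sim$gp$genes))
    planted <- sim$cis$truth$superenhancers
    planted <- planted[planted$context == ctx, ]
    sup <- sc$regions[sc$regions$is_super, ]
    expect_equal(nrow(sup), nrow(planted))
    expect_setequal(paste(sup$chrom, sup$start, sup$end),
                    paste(planted$chrom, planted$start, planted$end))

    scm <- call_super(stitch(peaks_for(sim$cis$h3k27me3, ctx),
                             genes = sim$gp$genes))
    pm <- sim$cis$truth$supermethylated
    pm <- pm[pm$context == ctx, ]
    supm <- scm$regions[scm$regions$is_super, ]
    expect_setequal(paste(supm$chrom, supm$start, supm$end),
                    paste(pm$chrom, pm$start, pm$end))
  }
})

test_that("build_state_map lays out the five classes", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 10000)
  ac <- iv("chr1", c(30000, 50000, 70000), c(31000, 51000, 71000),
           signal = c(4, 5, 300))
  sm <- build_state_map(ac, NULL, genes, promoter_window = 2000)
  expect_equal(sm$promoters$start, 8000)
  expect_equal(sm$promoters$end, 12000)
  expect_equal(nrow(sm$super_methylated) + nrow(sm$typical_methylated), 0)
  expect_equal(nrow(sm$super_enhancers), 1)
  expect_equal(sm$super_enhancers$start, 70000)
  expect_error(build_state_map(ac, NULL, genes[0, ]), "gene models")
})

test_that("assign_regions_to_genes matches the exhaustive scan with TAD and fallback rules", {
  genes <- tibble::tibble(gene_id = c("a", "b", "c"), chrom = "chr1",
                          tss = c(5000, 15000, 90000))
  tads <- tibble::tibble(chrom = "chr1", start = c(0, 80000),
                         end = c(20000, 85000),
                         tad_id = c("t1", "t2"))
  regions <- iv("chr1", c(1000, 81000, 95000), c(2000, 82000, 96000))
  got <- assign_regions_to_genes(regions, genes, tads)
  # region 1: TAD t1 contains genes a,b; region 2: t2 has no genes ->
  # nearest; region 3: outside any TAD -> nearest
  expect_setequal(got$gene_id[got$region_idx == 1], c("a", "b"))
  expect_equal(got$gene_id[got$region_idx == 2], "c")
  expect_equal(got$basis[got$region_idx == 2], "nearest")
  expect_equal(got$gene_id[got$region_idx == 3], "c")

  set.seed(41)
  for (rep in 1:10) {
    g <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                        chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                        tss = floor(runif(30, 0, 1e5)))
    td <- dplyr::bind_rows(
      tibble::tibble(chrom = "chr1", start = seq(0, 8e4, 2e4),
                     end = seq(2e4, 1e5, 2e4)),
      tibble::tibble(chrom = "chr2", start = c(0, 5e4), end = c(3e4, 9e4)))
    td$tad_id <- sprintf("t%02d", seq_len(nrow(td)))
    r <- random_intervals(40, max_pos = 1e5)
    got <- assign_regions_to_genes(r, g, td)[, c("region_idx", "gene_id")] |>
      dplyr::arrange(region_idx, gene_id)
    want <- brute_assign(r, g, td)
    expect_equal(as.data.frame(got), as.data.frame(want))
  }
})

test_that("loop anchoring counts loops touching constituents", {
  pk <- iv("chr1", c(0, 5000, 40000, 80000), c(1000, 6000, 41000, 81000),
           signal = c(200, 250, 3, 5))
  reg <- stitch(pk, stitch_distance = 12500)
  sc <- call_super(reg)
  expect_true(sc$regions$is_super[sc$regions$start == 0])
  loops <- tibble::tibble(chrom1 = "chr1", start1 = 100, end1 = 200,
                          chrom2 = "chr1", start2 = 90000, end2 = 91000)
  la <- loop_anchor_overlap(loops, sc$regions)
  expect_equal(sum(la$per_region$n_loops), 1)
  expect_equal(la$fraction_super_anchored, 1)

  none <- loop_anchor_overlap(loops[0, ], sc$regions)
  expect_equal(sum(none$per_region$n_loops), 0)
  expect_equal(none$fraction_super_anchored, 0)

  # anchor in the gap between constituents does not count
  gap_loop <- tibble::tibble(chrom1 = "chr1", start1 = 2000, end1 = 3000,
                             chrom2 = "chr1", start2 = 90000, end2 = 91000)
  la2 <- loop_anchor_overlap(gap_loop, sc$regions)
  expect_equal(sum(la2$per_region$n_loops), 0)
  # slop rescues it
  la3 <- loop_anchor_overlap(gap_loop, sc$regions, slop = 2500)
  expect_equal(sum(la3$per_region$n_loops), 1)
})

test_that("se_call tidiers and plot accessors work", {
  sc <- call_super(tibble::tibble(total_signal = c(1, 2, 3, 200)))
  td <- generics::tidy(sc)
  expect_true(all(c("rank", "is_super") %in% names(td)))
  gl <- generics::glance(sc)
  expect_equal(gl$n_super, 1)
  expect_s3_class(ggplot2::autoplot(sc), "ggplot")
})
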