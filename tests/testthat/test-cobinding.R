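# Co-occupancy, state annotation, context comparison, permutation
# enrichment and signal matrices.

mini_map <- function() {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", tss = 5000)
  ac <- iv("chr1", c(20000, 40000, 60000), c(21000, 41000, 61000),
           signal = c(5, 4, 400))
  me <- iv("chr1", c(80000, 90000, 95000), c(81000, 91000, 96000),
           signal = c(3, 2, 100))
  build_state_map(ac, me, genes, stitch_distance = 1000)
}

test_that("count_cobinding handles identical and disjoint peak sets", {
  same <- iv("chr1", 100, 700)
  sets <- list(MECOM = same, PAX8 = same, SOX17 = same, WT1 = same)
  ct <- count_cobinding(sets)
  expect_equal(nrow(ct$regions), 1)
  expect_equal(ct$regions$n_tfs_bound, 4)
  expect_equal(ct$per_tf$prop_cobound, rep(1, 4))

  apart <- lapply(c(0, 2000, 4000, 6000), function(o) iv("chr1", o, o + 500))
  names(apart) <- c("MECOM", "PAX8", "SOX17", "WT1")
  ct2 <- count_cobinding(apart)
  expect_equal(nrow(ct2$regions), 4)
  expect_equal(ct2$regions$n_tfs_bound, rep(1, 4))
  expect_equal(ct2$per_tf$prop_cobound, rep(0, 4))

  expect_error(count_cobinding(list(MECOM = same[0, ])), "nonempty")
})

test_that("co-binding membership matches brute force on fuzzed peak sets", {
  set.seed(55)
  for (rep in 1:8) {
    sets <- lapply(1:4, function(i) random_intervals(200))
    names(sets) <- c("MECOM", "PAX8", "SOX17", "WT1")
    ct <- count_cobinding(sets)
    for (tf in names(sets)) {
      expect_equal(ct$regions[[tf]],
                   brute_overlaps_any(ct$regions, sets[[tf]]))
    }
    # partition: bin counts sum to total regions, proportions to 1
    expect_equal(sum(table(ct$regions$n_tfs_bound)), nrow(ct$regions))
    expect_equal(sum(table(ct$regions$n_tfs_bound) / nrow(ct$regions)), 1)
    # every input peak overlaps >= 1 union region
    for (tf in names(sets)) {
      expect_true(all(brute_overlaps_any(sets[[tf]], ct$regions)))
    }
  }
})

test_that("annotate_state follows the fixed precedence and matches nested-if oracle", {
  sm <- mini_map()
  # promoter beats super-enhancer when both overlap
  both <- iv("chr1", c(4500, 60500), c(5500, 61500))
  lab <- annotate_state(both, sm)
  expect_equal(lab, c("promoter", "super_enhancer"))
  expect_equal(annotate_state(iv("chr1", 3e5, 3e5 + 100), sm), "none")

  set.seed(66)
  r <- random_intervals(100, chroms = "chr1", max_pos = 1.1e5)
  expect_equal(annotate_state(r, sm), brute_annotate(r, sm))
})

test_that("compare_contexts identity, disjoint and symmetry properties", {
  a <- iv("chr1", c(0, 1000), c(500, 1500))
  same <- compare_contexts(a, a)
  expect_equal(same$summary$fraction_common, 1)
  expect_equal(same$summary$specific_a + same$summary$specific_b, 0)

  b <- iv("chr1", c(5000, 7000), c(5500, 7500))
  disj <- compare_contexts(a, b)
  expect_equal(disj$summary$fraction_common, 0)

  set.seed(77)
  x <- random_intervals(150)
  y <- random_intervals(150)
  xy <- compare_contexts(x, y)
  yx <- compare_contexts(y, x)
  expect_equal(xy$summary$specific_a, yx$summary$specific_b)
  expect_equal(xy$summary$common, yx$summary$common)
  # brute-force classification of peaks
  expect_equal(sum(xy$summary$specific_a), sum(!brute_overlaps_any(x, y)))
  expect_equal(sum(xy$summary$specific_b), sum(!brute_overlaps_any(y, x)))
})

test_that("permutation test honours the p-value contract and edge cases", {
  gm <- genome_layout("chr1", 1e6)
  peaks <- list(PAX8 = iv("chr1", 1000, 2000))
  # zero TF peak overlap possible but never smaller than 1/(N+1)
  enh <- iv("chr1", 1000, 2000)
  pt <- enhancer_binding_permutation(enh, peaks, gm, n_permutations = 99,
                                     seed = 1)
  expect_gte(pt$p_value, 1 / 100)
  expect_equal(pt$observed, 1)
  expect_equal(length(pt$null_draws), 99)
  # reproducible under the seed
  pt2 <- enhancer_binding_permutation(enh, peaks, gm, n_permutations = 99,
                                      seed = 1)
  expect_identical(pt$null_draws, pt2$null_draws)

  # zero TF peaks: observed 0, p = 1
  none <- enhancer_binding_permutation(enh, list(PAX8 = iv("chr1", 1, 2)[0, ]),
                                       gm, n_permutations = 99, seed = 1)
  expect_equal(none$observed, 0)
  expect_equal(none$p_value, 1)

  expect_error(enhancer_binding_permutation(iv("chr1", 0, 1e6),
                                            peaks, genome_layout("chr1", 1e5)),
               "beyond|longer")
})

test_that("null placement frequency matches the exact placement probability", {
  # tiny genome: exhaustive placement enumeration is possible
  gm <- genome_layout("chr1", 1000)
  peaks <- list(TF = iv("chr1", c(100, 600), c(200, 650)))
  enh <- iv("chr1", 0, 50)   # length 50
  # exact P(overlap): start in [51,199] u [551,649] of 0..950
  hits <- sapply(0:950, function(s) (s < 200 && s + 50 > 100) ||
                   (s < 650 && s + 50 > 600))
  p_exact <- mean(hits)
  pt <- enhancer_binding_permutation(enh, peaks, gm, n_permutations = 4999,
                                     seed = 5)
  emp <- mean(pt$null_draws)
  se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(emp - p_exact), 3 * se)
})

test_that("bound-by-k distribution partitions the enhancer set", {
  sim <- default_sim()
  tfs <- c("MECOM", "PAX8", "SOX17", "WT1")
  sets <- lapply(stats::setNames(tfs, tfs), function(tf) {
    peaks_for(sim$cis$tf_peaks, "FTSEC", tf)
  })
  enh <- peaks_for(sim$cis$h3k27ac, "FTSEC")[, c("chrom", "start", "end")]
  pt <- enhancer_binding_permutation(enh, sets, sim$gp$genome,
                                     n_permutations = 49, seed = 1)
  expect_equal(sum(pt$bound_by_k$n), nrow(enh))
  expect_equal(sum(pt$bound_by_k$ratio), 1)
  expect_equal(pt$observed, 1 - pt$bound_by_k$ratio[pt$bound_by_k$k == 0])
})

test_that("signal_matrix reproduces flat, delta and fuzzed tracks", {
  track <- tibble::tibble(chrom = "chr1", start = 0, end = 50000, value = 4)
  centers <- iv("chr1", c(10000, 20000), c(11000, 21000))
  sm <- signal_matrix(track, centers, window = 3000, bin = 100,
                      library_size = 1e6)
  expect_true(all(abs(sm - 4) < 1e-12))

  delta <- tibble::tibble(chrom = "chr1", start = 10510, end = 10520, value = 7)
  sm2 <- signal_matrix(delta, centers, window = 3000, bin = 100,
                       library_size = 1e6)
  mid_bin <- 16   # window [9000,12000); bin 16 covers [10500,10600)
  expect_true(all(sm2[1, -mid_bin] == 0))
  expect_equal(sm2[1, mid_bin], 7 * 10 / 100)
  expect_true(all(sm2[2, ] == 0))

  expect_error(signal_matrix(track, centers, window = 3000, bin = 77),
               "divisible")

  set.seed(88)
  for (rep in 1:5) {
    tr <- random_intervals(60, chroms = "chr1", max_pos = 5e4)
    tr$value <- runif(60, 0, 10)
    ctr <- random_intervals(15, chroms = "chr1", max_pos = 4.5e4)
    ctr <- dplyr::arrange(ctr, chrom, start, end)
    got <- signal_matrix(tr, ctr, window = 2000, bin = 200, library_size = 2e6)
    want <- brute_signal_matrix(tr, ctr, 2000, 200, 2e6)
    expect_equal(unclass(got)[seq_along(want)], c(want), tolerance = 1e-10)
  }
})

test_that("edge windows are zero-padded and flagged", {
  track <- tibble::tibble(chrom = "chr1", start = 0, end = 5000, value = 2)
  centers <- iv("chr1", 100, 200)   # window extends below 0
  sm <- signal_matrix(track, centers, window = 3000, bin = 100,
                      library_size = 1e6, genome = genome_layout("chr1", 5000))
  expect_true(attr(sm, "clipped")[1])
  expect_true(all(sm[1, 1:13] == 0))   # bins before position 0
})
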