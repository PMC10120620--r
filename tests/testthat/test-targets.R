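# Direct / putative / indirect classification, rewiring summaries and the
# core-regulatory circuit.

hand_setup <- function() {
  genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                          tss = c(10000, 40000, 70000))
  tads <- tibble::tibble(chrom = "chr1", start = c(0, 30000, 60000),
                         end = c(30000, 60000, 90000),
                         tad_id = c("t1", "t2", "t3"))
  # PAX8: peak on gA promoter, peak in gB's TAD far from its promoter,
  # nothing in gC's TAD
  peaks <- tibble::tibble(tf = "PAX8", chrom = "chr1",
                          start = c(9500, 50000), end = c(10500, 50500),
                          locus_id = c("p1", "p2"))
  deg <- tibble::tibble(gene_id = c("gA", "gB", "gC"), tf = "PAX8",
                        context = "FTSEC", log2fc_1 = -1, log2fc_2 = -1,
                        mean_log2fc = -1, high_confidence = TRUE,
                        direction = "down")
  list(genes = genes, tads = tads, peaks = peaks, deg = deg)
}

test_that("classification implements promoter/TAD precedence", {
  h <- hand_setup()
  calls <- classify_targets(h$deg, h$peaks, h$genes, h$tads, context = "FTSEC")
  expect_equal(calls$mode[calls$gene_id == "gA"], "direct")
  expect_equal(calls$mode[calls$gene_id == "gB"], "putative")
  expect_equal(calls$mode[calls$gene_id == "gC"], "indirect")
  expect_equal(calls$evidence[calls$gene_id == "gA"], "p1")
  expect_equal(calls$evidence[calls$gene_id == "gB"], "p2")
  expect_equal(calls$evidence[calls$gene_id == "gC"], "none")
  # a promoter peak wins even when other peaks share the TAD
  extra <- dplyr::bind_rows(h$peaks,
                            tibble::tibble(tf = "PAX8", chrom = "chr1",
                                           start = 20000, end = 20500,
                                           locus_id = "p3"))
  calls2 <- classify_targets(h$deg, extra, h$genes, h$tads, context = "FTSEC")
  expect_equal(calls2$mode[calls2$gene_id == "gA"], "direct")
})

test_that("genes outside any TAD can be direct via promoter, else indirect", {
  h <- hand_setup()
  tads <- h$tads[h$tads$tad_id != "t2", ]
  calls <- classify_targets(h$deg, h$peaks, h$genes, tads, context = "FTSEC")
  expect_equal(calls$mode[calls$gene_id == "gB"], "indirect")
  expect_equal(calls$mode[calls$gene_id == "gA"], "direct")
})

test_that("nested TADs resolve to the smallest domain containing the TSS", {
  h <- hand_setup()
  nested <- dplyr::bind_rows(h$tads,
                             tibble::tibble(chrom = "chr1", start = 38000,
                                            end = 42000, tad_id = "t2small"))
  # in the small domain the evidence peak at 50000 is out of scope
  calls <- classify_targets(h$deg, h$peaks, h$genes, nested, context = "FTSEC")
  expect_equal(calls$mode[calls$gene_id == "gB"], "indirect")
})

test_that("DEGs missing from gene models are skipped with a warning", {
  h <- hand_setup()
  deg <- dplyr::bind_rows(h$deg,
                          tibble::tibble(gene_id = "ERCC-001", tf = "PAX8",
                                         context = "FTSEC", log2fc_1 = -1,
                                         log2fc_2 = -1, mean_log2fc = -1,
                                         high_confidence = TRUE,
                                         direction = "down"))
  expect_warning(calls <- classify_targets(deg, h$peaks, h$genes, h$tads,
                                           context = "FTSEC"), "skipping")
  expect_equal(nrow(calls), 3)
})

test_that("mode partition covers every high-confidence DEG exactly once", {
  sim <- default_sim()
  deg <- run_deg(sim)
  for (ctx in c("FTSEC", "HGSC")) {
    calls <- classify_targets(deg,
                              sim$cis$tf_peaks[sim$cis$tf_peaks$context == ctx, ],
                              sim$gp$genes, sim$gp$tads, context = ctx)
    hc <- deg[deg$high_confidence & deg$context == ctx, ]
    expect_equal(nrow(calls), nrow(hc))
    expect_equal(anyDuplicated(paste(calls$tf, calls$gene_id)), 0)
    expect_true(all(calls$mode %in% c("direct", "putative", "indirect")))
  }
})

test_that("classification is invariant to peak and TAD row order", {
  sim <- default_sim()
  deg <- run_deg(sim)
  pk <- sim$cis$tf_peaks[sim$cis$tf_peaks$context == "FTSEC", ]
  base <- classify_targets(deg, pk, sim$gp$genes, sim$gp$tads,
                           context = "FTSEC")
  set.seed(1)
  shuf <- classify_targets(deg, pk[sample(nrow(pk)), ], sim$gp$genes,
                           sim$gp$tads[sample(nrow(sim$gp$tads)), ],
                           context = "FTSEC")
  expect_equal(base[, c("tf", "gene_id", "mode", "sign")],
               shuf[, c("tf", "gene_id", "mode", "sign")])
})

test_that("rewiring summary conserves marginals", {
  h <- hand_setup()
  calls_a <- classify_targets(h$deg, h$peaks, h$genes, h$tads,
                              context = "FTSEC")
  same <- rewiring_summary(calls_a, calls_a)
  expect_equal(same$per_tf$shared, 3)
  expect_equal(same$per_tf$exclusive_a + same$per_tf$exclusive_b, 0)
  expect_true(all(same$transitions$mode_a == same$transitions$mode_b))

  other <- calls_a
  other$gene_id <- paste0(other$gene_id, "_x")
  disj <- rewiring_summary(calls_a, other)
  expect_equal(disj$per_tf$shared, 0)
  expect_equal(disj$per_tf$exclusive_a, 3)

  # marginals of the transition table equal shared counts
  calls_b <- calls_a
  calls_b$mode <- c("putative", "indirect", "direct")
  rw <- rewiring_summary(calls_a, calls_b)
  expect_equal(sum(rw$transitions$n), rw$per_tf$shared)
})

test_that("build_circuit signs edges by knockdown direction", {
  deg <- tibble::tibble(
    gene_id = c("MECOM", "SOX17", "SOX17", "gene_001"),
    tf = c("PAX8", "PAX8", "MECOM", "PAX8"),
    context = c("FTSEC", "FTSEC", "HGSC", "FTSEC"),
    log2fc_1 = c(-0.8, -0.6, 0.6, -2),
    log2fc_2 = c(-0.9, -0.7, 0.8, -2),
    mean_log2fc = c(-0.85, -0.65, 0.7, -2),
    high_confidence = TRUE,
    direction = c("down", "down", "up", "down"))
  cg <- build_circuit(deg)
  expect_equal(nrow(cg$edges), 3)   # the non-TF gene is excluded
  expect_equal(cg$edges$sign[cg$edges$target == "MECOM"], "activates")
  expect_equal(cg$edges$sign[cg$edges$regulator == "MECOM"], "represses")

  none <- build_circuit(deg[deg$gene_id == "gene_001", ])
  expect_equal(nrow(none$edges), 0)
  expect_s3_class(ggplot2::autoplot(cg), "ggplot")
})

test_that("planted circuit is recovered from the knockdown data", {
  sim <- default_sim()
  deg <- run_deg(sim)
  cg <- build_circuit(deg)
  planted <- sim$kd$truth$circuit
  got <- cg$edges
  got$psign <- ifelse(got$sign == "activates", "down", "up")
  expect_setequal(paste(got$regulator, got$target, got$context, got$psign),
                  paste(planted$regulator, planted$target, planted$context,
                        planted$sign))
})

test_that("read_tads accepts 3-column tables and BEDPE domains", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t0\t50000", "chr1\t50000\t100000"), p)
  td <- read_tads(p)
  expect_equal(nrow(td), 2)
  expect_equal(td$end, c(50000, 1e5))

  p2 <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t0\t5000\tchr1\t45000\t50000", p2)
  td2 <- read_tads(p2)
  expect_equal(td2$start, 0)
  expect_equal(td2$end, 50000)
})
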