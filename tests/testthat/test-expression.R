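# TPM, spike-in-anchored normalization, fold changes and the
# high-confidence rule.

toy_counts <- function(n_genes = 208, n_spike = 92, n_samples = 3, seed = 42) {
  set.seed(seed)
  n <- n_genes + n_spike
  tb <- tibble::tibble(
    gene_id = c(sprintf("g%03d", seq_len(n_genes)),
                sprintf("ERCC-%03d", seq_len(n_spike))),
    length = sample(500:3000, n, replace = TRUE),
    is_spikein = rep(c(FALSE, TRUE), c(n_genes, n_spike)))
  base <- 2^runif(n, 4, 12)
  for (s in seq_len(n_samples)) {
    tb[[paste0("s", s)]] <- base * rnorm(n, 1, 0.02)
  }
  tb
}

test_that("tpm follows the length-rate definition and columns sum to 1e6", {
  tb <- tibble::tibble(gene_id = c("a", "b"), length = c(1000, 1000),
                       is_spikein = FALSE, s1 = c(10, 90))
  out <- tpm(tb)
  expect_equal(out$s1, c(1e5, 9e5))

  one <- tpm(tibble::tibble(gene_id = "a", length = 777, is_spikein = FALSE,
                            s1 = 5))
  expect_equal(one$s1, 1e6)

  # length weighting: shorter gene gets proportionally higher TPM
  tb2 <- tibble::tibble(gene_id = c("a", "b"), length = c(500, 1000),
                        is_spikein = FALSE, s1 = c(50, 50))
  out2 <- tpm(tb2)
  expect_equal(out2$s1[1] / out2$s1[2], 2)

  big <- toy_counts()
  cols <- c("s1", "s2", "s3")
  sums <- colSums(as.matrix(tpm(big)[, cols]))
  expect_equal(unname(sums), rep(1e6, 3), tolerance = 1e-9)

  expect_warning(tpm(tibble::tibble(gene_id = "a", length = 100,
                                    is_spikein = FALSE, s1 = 0)), "all-zero")
  expect_error(tpm(tibble::tibble(gene_id = "a", length = 0,
                                  is_spikein = FALSE, s1 = 3)), "> 0")
})

test_that("loess_normalize leaves identical columns unchanged", {
  tb <- toy_counts()
  tp <- tpm(tb)
  tp$s2 <- tp$s1
  tp$s3 <- tp$s1
  nm <- loess_normalize(tp)
  expect_lt(max(abs(as.matrix(nm[, c("s1", "s2", "s3")]) -
                      as.matrix(tp[, c("s1", "s2", "s3")]))), 1e-6)
})

test_that("spike-in anchoring preserves biological shifts and removes technical ones", {
  tp <- tpm(toy_counts())
  gene <- !tp$is_spikein

  # genes x2, spike-ins untouched: the shift is certified and preserved
  bio <- tp
  bio$s2[gene] <- bio$s2[gene] * 2
  nb <- loess_normalize(bio)
  shift <- median(log2(nb$s2[gene] / nb$s1[gene]))
  expect_gt(shift, 0.9)
  anchor_m <- median(log2(nb$s2[!gene] / nb$s1[!gene]))
  expect_lt(abs(anchor_m), 0.05)

  # everything x2 including spike-ins: technical, removed
  tech <- tp
  tech$s2 <- tech$s2 * 2
  nt <- loess_normalize(tech)
  expect_lt(abs(median(log2(nt$s2 / nt$s1))), 0.05)

  few <- tp[c(which(gene), which(!gene)[1:5]), ]
  expect_error(loess_normalize(few), "insufficient anchor")
})

test_that("log2fc computes knockdown minus pooled controls per cell line", {
  tb <- toy_counts(n_samples = 6)
  names(tb)[4:9] <- c("L1_control_1_r1", "L1_control_2_r1", "L1_siPAX8_r1",
                      "L2_control_1_r1", "L2_control_2_r1", "L2_siPAX8_r1")
  samples <- tibble::tibble(
    sample = names(tb)[4:9],
    cell_line = rep(c("L1", "L2"), each = 3),
    context = "FTSEC",
    condition = rep(c("control_1", "control_2", "siPAX8"), 2),
    replicate = 1)
  # knockdown equal to controls: log2fc 0
  tb$L1_siPAX8_r1 <- tb$L1_control_1_r1
  tb$L1_control_2_r1 <- tb$L1_control_1_r1
  out <- log2fc(tpm(tb), samples, "PAX8", pseudocount = 0)
  expect_equal(out$log2fc[out$cell_line == "L1"],
               rep(0, sum(out$cell_line == "L1")))

  # knockdown exactly x2 the controls: log2fc 1 everywhere (pc = 0)
  tb$L2_control_2_r1 <- tb$L2_control_1_r1
  tb$L2_siPAX8_r1 <- tb$L2_control_1_r1 * 2
  tp <- tb   # bypass TPM renormalization: feed as already-normalized values
  out2 <- log2fc(tp, samples, "siPAX8", pseudocount = 0)
  expect_equal(out2$log2fc[out2$cell_line == "L2"],
               rep(1, sum(out2$cell_line == "L2")))

  expect_error(log2fc(tp, samples, "MECOM"), "not present")
})

test_that("high-confidence rule matches hand enumeration on a 12-row table", {
  rows <- tibble::tribble(
    ~gene_id, ~l1,   ~l2,   ~want_hc, ~want_dir,
    "g01",    -0.6,  -0.7,  TRUE,     "down",
    "g02",    -0.6,   0.6,  FALSE,    NA,        # discordant
    "g03",    -0.5,  -0.5,  TRUE,     "down",    # inclusive boundary
    "g04",     0.5,   0.5,  TRUE,     "up",
    "g05",     0.49,  0.8,  FALSE,    NA,        # one line short
    "g06",     0.0,   0.0,  FALSE,    NA,
    "g07",     2.4,   0.51, TRUE,     "up",
    "g08",    -0.51, -2.4,  TRUE,     "down",
    "g09",     0.5,  -0.5,  FALSE,    NA,
    "g10",    -0.49, -0.49, FALSE,    NA,
    "g11",     1.0,   0.4,  FALSE,    NA,
    "g12",    -3.0,  -0.5,  TRUE,     "down")
  lfc <- dplyr::bind_rows(
    tibble::tibble(gene_id = rows$gene_id, tf = "PAX8", cell_line = "A",
                   context = "FTSEC", log2fc = rows$l1),
    tibble::tibble(gene_id = rows$gene_id, tf = "PAX8", cell_line = "B",
                   context = "FTSEC", log2fc = rows$l2))
  deg <- call_high_confidence(lfc, threshold = 0.5)
  deg <- deg[match(rows$gene_id, deg$gene_id), ]
  expect_equal(deg$high_confidence, rows$want_hc)
  expect_equal(deg$direction[deg$high_confidence],
               rows$want_dir[rows$want_hc])

  single <- lfc[lfc$cell_line == "A", ]
  expect_error(call_high_confidence(single), "two cell lines")
  expect_silent(call_high_confidence(single, allow_single = TRUE))
})

test_that("cyclic loess agrees with limma on an unanchored two-sample case", {
  skip_if_not_installed("limma")
  tb <- toy_counts(n_samples = 2)
  tp <- tpm(tb)
  tp$s2 <- tp$s2 * 1.7
  ours <- loess_normalize(tp, anchor = "all_genes", max_pass = 3)
  om <- log2(as.matrix(ours[, c("s1", "s2")]) + 1)
  lm <- limma::normalizeCyclicLoess(log2(as.matrix(tp[, c("s1", "s2")]) + 1),
                                    span = 0.6, iterations = 3)
  # same global correction to within smoother details
  expect_lt(abs(median(om[, 2] - om[, 1]) - median(lm[, 2] - lm[, 1])), 0.02)
})
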