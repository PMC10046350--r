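test_that("the ploidy-aware copy-number transform is exact and invertible", {
  expect_identical(rcn_to_acn(2, 2), 6)
  expect_identical(rcn_to_acn(0, 2), 0)
  expect_identical(rcn_to_acn(2, 3), 9)
  expect_equal(acn_to_rcn(6, 2), 2)
  expect_equal(acn_to_rcn(0, 3), 0)
  expect_error(rcn_to_acn(1, 0), "ploidy")
  expect_error(acn_to_rcn(-1, 2), "non-negative")

  set.seed(7)
  acn <- runif(1000, 0, 50)
  ploidy <- sample(c(2, 3, 4), 1000, replace = TRUE)
  expect_lt(max(abs(rcn_to_acn(acn_to_rcn(acn, ploidy), ploidy) - acn)), 1e-9)
})

test_that("relative and absolute call modes agree at ploidy 2 and differ off it", {
  # diploid at RCN 2 (= 6 copies), triploid at 7 copies (RCN ~ 1.74)
  vals <- matrix(c(2.0, acn_to_rcn(7, 3), 0.5, 0.5), 1, 4)
  rcn <- toy_matrix(vals, "copy_number", genes = "REF",
                    samples = c("dip", "tri", "dip2", "tri2"))
  samples <- data.frame(sample_id = c("dip", "tri", "dip2", "tri2"),
                        lineage = "x", ploidy = c(2, 3, 2, 3),
                        source = "cell_line")
  rel <- call_amplifications(rcn, samples, "REF", mode = "relative")
  abs_ <- call_amplifications(rcn, samples, "REF", mode = "absolute")
  expect_equal(rel$amplified_samples, "dip")
  expect_setequal(abs_$amplified_samples, c("dip", "tri"))
  expect_equal(abs_$mode_discrepancy, "tri")
  expect_equal(unname(abs_$acn[c("dip", "tri")]), c(6, 7), tolerance = 1e-12)

  zero <- toy_matrix(matrix(0, 1, 3), "copy_number", genes = "REF")
  expect_length(call_amplifications(zero, NULL, "REF")$amplified_samples, 0L)
  expect_error(call_amplifications(rcn, samples, "NOPE"), "surrogate")
})

test_that("mode equivalence holds at ploidy 2 for every sample of a fixture", {
  b <- default_bundle()
  dip <- b$samples$sample_id[b$samples$ploidy == 2]
  rel <- call_amplifications(b$rcn, b$samples, b$truth$reference_gene, "relative")
  abs_ <- call_amplifications(b$rcn, b$samples, b$truth$reference_gene, "absolute")
  expect_setequal(intersect(rel$amplified_samples, dip),
                  intersect(abs_$amplified_samples, dip))
})

test_that("coamplicon construction keeps correlated genes and drops noise", {
  set.seed(11)
  n <- 200
  ref <- c(rnorm(n / 2, 0.9, 0.1), rnorm(n / 2, 2.5, 0.3))
  vals <- rbind(ref, ref, rnorm(n))
  rcn <- toy_matrix(vals, "copy_number", genes = c("REF", "TWIN", "NOISE"))
  amp <- find_coamplified(rcn, "REF", r_threshold = 0.7)
  expect_setequal(amp$coamplified$gene, c("REF", "TWIN"))
  expect_equal(amp$coamplified$r[amp$coamplified$gene == "REF"], 1)
  expect_equal(amp$coamplified$r[amp$coamplified$gene == "TWIN"], 1)

  flat <- toy_matrix(matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE),
                     "copy_number", genes = c("REF", "G2"))
  expect_error(find_coamplified(flat, "REF"), "no variation")
})

test_that("the planted coamplicon is recovered exactly from the fixture", {
  b <- default_bundle()
  amp <- find_coamplified(b$rcn, b$truth$reference_gene)
  expect_setequal(amp$coamplified$gene, b$truth$coamplified_genes)
  expect_true(all(amp$coamplified$r >= 0.7))
})

test_that("amplification frequencies are per-lineage proportions in [0, 1]", {
  rcn <- toy_matrix(matrix(c(2.5, 2.5, 0.5, 0.5), 1, 4), "copy_number",
                    genes = "REF", samples = paste0("s", 1:4))
  samples <- data.frame(sample_id = paste0("s", 1:4), lineage = "lung",
                        ploidy = 2, source = "cell_line")
  calls <- call_amplifications(rcn, samples, "REF")
  freq <- amplification_frequency(calls, samples)
  expect_equal(freq$frequency, 0.5)

  b <- default_bundle()
  calls_b <- call_amplifications(b$rcn, b$samples, b$truth$reference_gene, "absolute")
  freq_b <- amplification_frequency(calls_b, b$samples)
  expect_true(all(freq_b$frequency >= 0 & freq_b$frequency <= 1))
  pooled <- sum(freq_b$n_amplified) / sum(freq_b$n)
  expect_lt(abs(pooled - 0.3), 3 * sqrt(0.3 * 0.7 / sum(freq_b$n)))

  # invariant to sample order
  perm <- sample(seq_len(nrow(b$samples)))
  freq_p <- amplification_frequency(calls_b, b$samples[perm, ])
  expect_equal(freq_p[order(freq_p$lineage), ], freq_b[order(freq_b$lineage), ],
               ignore_attr = TRUE)
})

test_that("similarity tiers partition the correlation line at 0.4 and 0.7", {
  for (case in list(list(r = 1, tier = "high"), list(r = 0.75, tier = "high"),
                    list(r = 0.5, tier = "moderate"), list(r = 0.1, tier = "weak"))) {
    pr <- similarity_pair(case$r)
    rep <- lineage_similarity(pr$tumor, pr$cellline)
    expect_equal(rep$r, case$r, tolerance = 1e-10)
    expect_equal(rep$tier, case$tier)
  }

  # degenerate: zero-variance tumor frequencies (amplification rare) or too
  # few reference genes
  pr <- similarity_pair(0.5)
  pr$tumor$frequency <- 0
  expect_equal(lineage_similarity(pr$tumor, pr$cellline)$tier, "not_evaluable")
  pr2 <- similarity_pair(0.9, n_genes = 2)
  expect_equal(lineage_similarity(pr2$tumor, pr2$cellline)$tier, "not_evaluable")
})

test_that("co-occurrence reports Jaccard overlap and conditional frequencies", {
  mk <- function(gene, ids) {
    structure(list(reference_gene = gene, threshold_mode = "absolute",
                   amplified_samples = ids,
                   acn = stats::setNames(rep(7, 10), paste0("s", 1:10)),
                   mode_discrepancy = character()),
              class = "amplification_calls")
  }
  same <- cooccurrence_matrix(list(mk("A", paste0("s", 1:4)), mk("B", paste0("s", 1:4))))
  expect_equal(same$jaccard, 1)
  expect_true(same$flagged)
  disj <- cooccurrence_matrix(list(mk("A", paste0("s", 1:4)), mk("B", paste0("s", 5:8))))
  expect_equal(disj$jaccard, 0)
  expect_equal(disj$p_a_given_b, 0)

  # two planted amplicons sharing half their lines: Jaccard near 1/3
  cfg <- small_config(extra_amplicons = list(
    list(span = c(201L, 210L), share_with_primary = 0.5)))
  cn <- simulate_copy_number(cfg)
  cs <- lapply(cn$truth$amplicons, function(a) mk(a$reference_gene, a$amplified_lines))
  co <- cooccurrence_matrix(cs)
  expect_lt(abs(co$jaccard - 1 / 3), 0.1)
})
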