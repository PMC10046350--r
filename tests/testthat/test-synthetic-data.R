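test_that("generator is deterministic and validates its config", {
  cfg <- small_config()
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(unclass(b1$rcn), unclass(b2$rcn))
  expect_identical(unclass(b1$effects), unclass(b2$effects))
  expect_identical(unclass(b1$expression), unclass(b2$expression))
  expect_identical(b1$survival, b2$survival)
  expect_identical(b1$truth$amplified_lines, b2$truth$amplified_lines)

  expect_error(sim_config(amp_copies_range = c(4, 10)), "amp_copies_range")
  expect_error(sim_config(dependent_genes = 1L), "amplicon_span")
  expect_error(sim_config(amplified_fraction = 1.2), "amplified_fraction")
  expect_error(sim_config(survival_hr = 0), "survival_hr")
  expect_error(simulate_gene_effects(small_config(delta_effect = 0.5),
                                     small_bundle()$truth),
               "negative")
})

test_that("no amplification is planted when amplified_fraction = 0", {
  cn <- simulate_copy_number(small_config(amplified_fraction = 0))
  span <- cn$truth$coamplified_genes
  expect_true(all(cn$rcn[span, ] < 2))
  expect_length(cn$truth$amplified_lines, 0L)
})

test_that("planted amplified fraction is recovered by calling at the reference gene", {
  b <- default_bundle()
  calls <- call_amplifications(b$rcn, b$samples, b$truth$reference_gene,
                               mode = "absolute")
  frac <- length(calls$amplified_samples) / ncol(b$rcn)
  se <- sqrt(0.3 * 0.7 / ncol(b$rcn))
  expect_lt(abs(frac - 0.3), 3 * se)
  expect_setequal(calls$amplified_samples, b$truth$amplified_lines)
})

test_that("non-essential genes center at zero and planted shifts are recovered", {
  cfg <- sim_config(n_genes = 1000, n_lines = 100,
                    amplicon_span = c(501L, 510L), reference_index = 505L,
                    dependent_genes = c(503L, 507L), dosage_genes = c(503L, 507L))
  cn <- simulate_copy_number(cfg)
  eff <- simulate_gene_effects(cfg, cn$truth)
  non_ess <- setdiff(rownames(eff), cn$truth$dependent_genes)
  vals <- unclass(eff)[non_ess, ]
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)

  # planted dependent gene: group difference recovers delta = -0.5
  amp <- colnames(eff) %in% cn$truth$amplified_lines
  g <- cn$truth$dependent_genes[1L]
  diff <- mean(eff[g, amp]) - mean(eff[g, !amp])
  se_d <- cfg$effect_noise_sd * sqrt(1 / sum(amp) + 1 / sum(!amp))
  expect_lt(abs(diff - (-0.5)), 3 * se_d)
})

test_that("the noiseless limit reproduces the planted shift exactly", {
  cfg <- small_config(effect_noise_sd = 0)
  cn <- simulate_copy_number(cfg)
  eff <- simulate_gene_effects(cfg, cn$truth)
  amp <- colnames(eff) %in% cn$truth$amplified_lines
  g <- cn$truth$dependent_genes[1L]
  expect_equal(mean(eff[g, amp]) - mean(eff[g, !amp]), -0.5)
})

test_that("dosage genes track copy number and buffered genes do not", {
  cfg <- small_config(expr_noise_sd = 0, lineage_sd = 0)
  cn <- simulate_copy_number(cfg)
  expr <- simulate_expression(cfg, cn$truth, cn$rcn)
  g <- cn$truth$dosage_genes[1L]
  expect_equal(stats::cor(expr[g, ], cn$rcn[g, ]), 1)

  # buffered gene at default noise: below the 95% null bound
  cfg2 <- sim_config()
  cn2 <- simulate_copy_number(cfg2)
  expr2 <- simulate_expression(cfg2, cn2$truth, cn2$rcn)
  buffered <- setdiff(cn2$truth$dependent_genes, cn2$truth$dosage_genes)[1L]
  r <- stats::cor(expr2[buffered, ], cn2$rcn[buffered, ])
  expect_lt(abs(r), 1.96 / sqrt(ncol(expr2) - 1))
})

test_that("lineage offsets structure expression between, not within, lineages", {
  cfg <- small_config(expr_noise_sd = 0.1, lineage_sd = 2, dosage_slope = 0)
  cn <- simulate_copy_number(cfg)
  expr <- simulate_expression(cfg, cn$truth, cn$rcn)
  g <- rownames(expr)[1L]
  by_lin <- split(expr[g, cn$samples$sample_id], cn$samples$lineage)
  lineage_means <- vapply(by_lin, mean, 0)
  within_sd <- mean(vapply(by_lin, stats::sd, 0))
  # between-lineage spread dominates the within-lineage noise
  expect_gt(stats::sd(lineage_means), 3 * within_sd)
})

test_that("survival generator matches its exponential model", {
  # null: hazard ratio 1 gives uniform log-rank p over repeats
  ps <- vapply(1:50, function(s) {
    cfg <- small_config(survival_hr = 1, censor_time = Inf, other_hazard = 0,
                        seed = 5000L + s)
    sv <- simulate_survival(cfg)
    os <- sv[sv$endpoint == "OS", ]
    a <- os[os$group == "amplified", ]
    b <- os[os$group != "amplified", ]
    logrank_test(a$time, a$event, b$time, b$event)$p_value
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(sum(ps < 0.05) / 50, 0.2)

  # hazard ratio 3, large arms, no censoring: O/E recovery within 30%
  cfg <- sim_config(survival_hr = 3, n_tumors = 1000, amplified_fraction = 0.5,
                    censor_time = Inf, other_hazard = 0)
  sv <- simulate_survival(cfg)
  os <- sv[sv$endpoint == "OS", ]
  a <- os[os$group == "amplified", ]
  b <- os[os$group != "amplified", ]
  hr <- logrank_test(a$time, a$event, b$time, b$event)$hr_oe
  expect_lt(abs(hr - 3) / 3, 0.3)

  # baseline hazard log(2), HR 1: KM median at one time unit (within 10%)
  cfg2 <- sim_config(survival_hr = 1, n_tumors = 1000, censor_time = Inf,
                     other_hazard = 0, baseline_hazard = log(2))
  sv2 <- simulate_survival(cfg2)
  os2 <- sv2[sv2$endpoint == "OS", ]
  expect_lt(abs(km_estimate(os2$time, os2$event)$median - 1), 0.1)
})

test_that("DSS censors other-cause deaths that OS counts as events", {
  cfg <- small_config(other_hazard = 0.5, censor_time = Inf)
  sv <- simulate_survival(cfg)
  os <- sv[sv$endpoint == "OS", ]
  dss <- sv[sv$endpoint == "DSS", ]
  expect_identical(os$time, dss$time)
  expect_true(all(dss$event <= os$event))
  expect_gt(sum(os$event) - sum(dss$event), 0)
})

test_that("fixture bundles roundtrip through disk and keep their manifest", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_fixture_bundle(b, dir)
  rt <- read_fixture_bundle(dir)
  expect_equal(unclass(rt$rcn), unclass(b$rcn))
  expect_equal(unclass(rt$effects), unclass(b$effects))
  expect_equal(unclass(rt$expression), unclass(b$expression))
  expect_equal(rt$samples, b$samples)
  expect_equal(rt$survival$time, b$survival$time)
  expect_equal(lapply(rt$positional_sets, as.character),
               lapply(b$positional_sets, as.character))
  expect_equal(rt$annotations, b$annotations)
  expect_setequal(rt$truth$dependent_genes, b$truth$dependent_genes)
  expect_setequal(rt$truth$coamplified_genes, b$truth$coamplified_genes)
  expect_setequal(rt$truth$amplified_lines, b$truth$amplified_lines)

  # manifest invariants
  expect_true(all(b$truth$dependent_genes %in% b$truth$coamplified_genes))
  expect_true(all(b$truth$dosage_genes %in% rownames(b$expression)))
})

test_that("a second amplicon can share a stated fraction of amplified lines", {
  cfg <- small_config(extra_amplicons = list(
    list(span = c(201L, 210L), share_with_primary = 0.5)))
  cn <- simulate_copy_number(cfg)
  a <- cn$truth$amplicons[[1L]]$amplified_lines
  b <- cn$truth$amplicons[[2L]]$amplified_lines
  jac <- length(intersect(a, b)) / length(union(a, b))
  # sharing half of equal-size sets gives Jaccard 1/3
  expect_lt(abs(jac - 1 / 3), 0.1)
})
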