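test_that("hypergeometric overlap p equals combinatorial enumeration", {
  # full-overlap case: drawing all 5 of 5 marked genes from 10 is 1/C(10,5)
  uni <- sprintf("u%02d", 1:10)
  ov <- hypergeom_overlap(uni[1:5], uni[1:5], uni)
  expect_equal(ov$k, 5L)
  expect_equal(ov$gene_ratio, 1)
  expect_equal(ov$p_value, 1 / 252, tolerance = 1e-12)

  # zero overlap is never evidence: p = 1
  ov0 <- hypergeom_overlap(uni[1:4], uni[5:8], uni)
  expect_equal(ov0$k, 0L)
  expect_equal(ov0$p_value, 1)

  # query = universe forces k = K with p = 1
  ovf <- hypergeom_overlap(uni, uni[2:4], uni)
  expect_equal(ovf$k, ovf$K)
  expect_equal(ovf$p_value, 1)

  expect_error(hypergeom_overlap(c(uni[1], "stranger"), uni[1:3], uni), "stranger")

  # exhaustive agreement for every feasible (N, K, n, k) with N <= 15
  worst <- 0
  for (N in 2:15) {
    g <- sprintf("x%02d", 1:N)
    for (K in 1:N) for (n in 1:N) {
      for (k in max(0, K + n - N):min(K, n)) {
        query <- c(g[seq_len(k)], g[K + seq_len(n - k)])
        got <- hypergeom_overlap(query, g[seq_len(K)], g)
        expect_equal(got$k, k)
        worst <- max(worst, abs(got$p_value - hyper_tail_oracle(k, K, n, N)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("overlap analysis ranks the band holding the query first", {
  sets <- list(band1 = sprintf("x%02d", 1:10), band2 = sprintf("x%02d", 11:20),
               band3 = sprintf("x%02d", 21:30))
  uni <- sprintf("x%02d", 1:30)
  res <- overlap_analysis(sprintf("x%02d", 2:6), sets, uni)
  expect_equal(res$set_name[1L], "band1")
  expect_equal(res$k[1L], 5L)
  expect_equal(res$gene_ratio[1L], 0.5)
  expect_true(all(res$q_value >= res$p_value - 1e-15))

  expect_warning(empty <- overlap_analysis(character(), sets, uni), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("random queries rarely reach significance across a band collection", {
  b <- default_bundle()
  sets <- b$positional_sets
  uni <- rownames(b$rcn)
  set.seed(21)
  minq <- vapply(1:20, function(i) {
    min(overlap_analysis(sample(uni, 10), sets, uni)$q_value)
  }, 0)
  expect_gte(mean(minq > 0.05), 0.9)
})

test_that("the GSEA rank score orders dependencies by strength and direction", {
  screen <- data.frame(
    gene_id = c("a", "b", "c", "d"),
    delta = c(-1, -0.2, 0.3, -0.5),
    p_value = c(1e-4, 0.4, 0.01, 1e-4),
    q_value = c(0.01, 0.5, 0.05, 0.01))
  ranked <- rank_for_gsea(screen)
  expect_equal(ranked$gene_id, c("a", "d", "b", "c"))  # a ties d on q, wins on |delta|
  expect_lt(ranked$score[ranked$gene_id == "c"], 0)    # delta > 0 sinks

  # full tie resolves lexicographically and reproducibly
  tied <- data.frame(gene_id = c("z", "y"), delta = c(-1, -1),
                     p_value = c(0.2, 0.2), q_value = c(0.3, 0.3))
  expect_equal(rank_for_gsea(tied)$gene_id, c("y", "z"))
  expect_equal(rank_for_gsea(tied[2:1, ])$gene_id, c("y", "z"))
})

test_that("the running-sum enrichment score matches hand computations", {
  scores <- c(5, 4, 3, 2, 1)
  # top-2 set, unweighted: climbs 0.5 then 1.0 without ever stepping down
  expect_equal(ampdep:::gsea_es(scores, c(1, 2), weight = 0), 1.0)
  # ranks {1, 3}, weighted: 5/8, 5/8 - 1/3, then + 3/8 = 2/3
  expect_equal(ampdep:::gsea_es(scores, c(1, 3), weight = 1), 2 / 3, tolerance = 1e-12)
})

test_that("the fast enrichment score agrees with a literal walk and with fgsea", {
  set.seed(17)
  for (i in 1:100) {
    N <- sample(5:60, 1)
    m <- sample(1:(N - 1), 1)
    scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    hits <- sort(sample.int(N, m))
    w <- sample(c(0, 1, 1.5), 1)
    fast <- ampdep:::gsea_es(scores, hits, w)
    expect_equal(fast, es_walk_oracle(scores, hits, w), tolerance = 1e-12)
    expect_gte(fast, -1); expect_lte(fast, 1)
    # reversing all rank-score signs (and hence the list) negates ES; checked
    # at weight 1, where exact magnitude ties between the positive and
    # negative extremes (which resolve by the positive-preference rule, not
    # by negation) have probability zero
    if (w == 1) {
      expect_equal(ampdep:::gsea_es(rev(-scores), N + 1 - rev(hits), w), -fast,
                   tolerance = 1e-9)
    }
  }

  ref <- fgsea::calcGseaStat
  set.seed(18)
  for (i in 1:50) {
    N <- sample(10:100, 1)
    m <- sample(2:5, 1)
    scores <- sort(rnorm(N, 1), decreasing = TRUE)
    hits <- sort(sample.int(N, m))
    expect_equal(ampdep:::gsea_es(scores, hits, 1),
                 ref(scores, hits, gseaParam = 1), tolerance = 1e-10)
  }
})

test_that("preranked GSEA is reproducible and calibrated against enumeration", {
  ranked <- data.frame(gene_id = letters[1:8],
                       score = c(4, 3, 2.5, 1.5, 1, 0.5, -0.5, -1.2))
  target <- c("a", "c", "e")
  g1 <- preranked_gsea(ranked, target, n_perm = 2000, seed = 42)
  g2 <- preranked_gsea(ranked, target, n_perm = 2000, seed = 42)
  expect_identical(g1$es, g2$es)
  expect_identical(g1$nominal_p, g2$nominal_p)
  expect_equal(sign(g1$nes), sign(g1$es))
  expect_true(g1$fdr_q >= 0 && g1$fdr_q <= 1)
  expect_true(all(g1$leading_edge %in% target))

  # exhaustive null over all C(8,3) same-size subsets
  subsets <- utils::combn(8, 3)
  all_es <- apply(subsets, 2, function(s) ampdep:::gsea_es(ranked$score, s, 1))
  same_sign <- all_es[sign(all_es) == sign(g1$es) | all_es == 0]
  p_exact <- mean(abs(same_sign) >= abs(g1$es))
  expect_lt(abs(g1$nominal_p - p_exact), 0.06)

  expect_error(preranked_gsea(ranked, c("zz"), n_perm = 10), "intersect")
  expect_error(preranked_gsea(ranked, letters[1:8], n_perm = 10), "entire")
})

test_that("coamplified genes enrich at the top of the fixture's dependency ranking", {
  b <- default_bundle()
  calls <- call_amplifications(b$rcn, b$samples, b$truth$reference_gene, "absolute")
  amp <- find_coamplified(b$rcn, b$truth$reference_gene)
  screen <- screen_amplicon(b$effects, calls, amp)
  ranked <- rank_for_gsea(screen)
  coamp <- setdiff(amp$coamplified$gene, amp$reference_gene)
  res <- preranked_gsea(ranked, coamp, n_perm = 2000, seed = 7)
  expect_gt(res$es, 0)
  expect_gt(res$nes, 1)
  expect_lt(res$fdr_q, 0.05)
})
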