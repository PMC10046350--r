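#' Copy-number to expression correlation for prioritized genes
#'
#' The immediate downstream effect of amplification should be
#' overexpression, but feedback in transcription can buffer it. For each
#' gene, Pearson-correlates its stored relative copy number (or its
#' surrogate's — e.g. a coamplified pseudogene's copy-number row when the
#' gene itself has none) against its expression across the selected samples,
#' then corrects the family of genes with Benjamini-Hochberg. Pairs with a
#' missing value in either matrix are dropped pairwise; genes with fewer
#' than `min_samples` complete pairs or zero variance are reported
#' inconclusive (`NA` correlation) rather than tested.
#'
#' @param rcn Copy-number [gene_matrix()].
#' @param expression Expression [gene_matrix()].
#' @param genes Genes to assess.
#' @param sample_ids Samples defining the scope (e.g. one lineage); default
#'   all shared samples.
#' @param surrogate_map Optional `target -> surrogate` map applied to the
#'   copy-number lookup (see [resolve_surrogates()]).
#' @param min_samples Minimum complete pairs (default 5).
#' @return A data.frame per gene: `gene_id`, `cn_gene`, `n`, `r`, `p_value`,
#'   `q_value`.
#' @export
cn_expression_correlation <- function(rcn, expression, genes,
                                      sample_ids = NULL, surrogate_map = list(),
                                      min_samples = 5L) {
  assert_role(rcn, "copy_number")
  assert_role(expression, "expression")
  shared <- intersect(colnames(rcn), colnames(expression))
  if (!is.null(sample_ids)) shared <- intersect(shared, sample_ids)
  rows <- lapply(genes, function(g) {
    cn_gene <- tryCatch(as.character(resolve_surrogates(surrogate_map, g, rcn)),
                        error = function(e) NA_character_)
    if (is.na(cn_gene) || !g %in% rownames(expression)) {
      return(data.frame(gene_id = g, cn_gene = cn_gene, n = 0L, r = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    pair_cor_row(g, cn_gene, rcn[cn_gene, shared], expression[g, shared], min_samples)
  })
  res <- do.call(rbind, rows)
  res$q_value <- benjamini_hochberg(res$p_value)
  rownames(res) <- NULL
  res
}

pair_cor_row <- function(gene, cn_gene, x, y, min_samples) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_samples || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(data.frame(gene_id = gene, cn_gene = cn_gene, n = n, r = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  data.frame(gene_id = gene, cn_gene = cn_gene, n = n,
             r = unname(ct$estimate), p_value = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Expression to dependency correlation
#'
#' Tests whether mRNA level predicts knockout vulnerability: Pearson
#' correlation of expression against gene-effect score across the selected
#' samples, per gene, with Benjamini-Hochberg across the gene family. A
#' negative r means higher expression goes with a stronger dependency (more
#' negative effect).
#'
#' @param expression Expression [gene_matrix()].
#' @param effects Gene-effect [gene_matrix()].
#' @inheritParams cn_expression_correlation
#' @return A data.frame per gene: `gene_id`, `n`, `r`, `p_value`, `q_value`.
#' @export
expression_dependency_correlation <- function(expression, effects, genes,
                                              sample_ids = NULL, min_samples = 5L) {
  assert_role(expression, "expression")
  assert_role(effects, "gene_effect")
  shared <- intersect(colnames(expression), colnames(effects))
  if (!is.null(sample_ids)) shared <- intersect(shared, sample_ids)
  rows <- lapply(genes, function(g) {
    if (!g %in% rownames(expression) || !g %in% rownames(effects)) {
      return(data.frame(gene_id = g, cn_gene = NA_character_, n = 0L,
                        r = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE))
    }
    pair_cor_row(g, NA_character_, expression[g, shared], effects[g, shared], min_samples)
  })
  res <- do.call(rbind, rows)
  res$cn_gene <- NULL
  res$q_value <- benjamini_hochberg(res$p_value)
  rownames(res) <- NULL
  res
}

#' Classify expression as a dependency biomarker
#'
#' Joins the two correlation families and applies a fixed, configurable
#' rule: a gene's expression is called an `expression_biomarker` when copy
#' number drives expression (`q_cn_expr < q_threshold` and
#' `r_cn_expr >= r_threshold`) *and* expression predicts dependency
#' (`q_expr_dep < q_threshold` and `r_expr_dep <= -r_threshold`). A screen
#' hit failing either condition is `copy_number_only` — its copy number, not
#' its mRNA, is the usable biomarker. Everything else is `inconclusive`.
#' The default `r_threshold = 0.4` mirrors the moderate-correlation tier
#' used for the tumor/cell-line similarity analysis.
#'
#' @param cn_expr Output of [cn_expression_correlation()].
#' @param expr_dep Output of [expression_dependency_correlation()].
#' @param is_screen_hit Logical vector (or character vector of hit gene ids)
#'   marking which assessed genes are significant screen dependencies.
#' @param r_threshold,q_threshold Rule cutoffs (defaults 0.4 and 0.05).
#' @return A data.frame per gene: `gene_id`, `r_cn_expr`, `q_cn_expr`,
#'   `r_expr_dep`, `q_expr_dep`, `screen_hit`, `classification`.
#' @export
classify_biomarker <- function(cn_expr, expr_dep, is_screen_hit,
                               r_threshold = 0.4, q_threshold = 0.05) {
  genes <- cn_expr$gene_id
  stopifnot(identical(sort(genes), sort(expr_dep$gene_id)))
  ed <- expr_dep[match(genes, expr_dep$gene_id), ]
  hit <- if (is.character(is_screen_hit)) genes %in% is_screen_hit else is_screen_hit
  dosage_ok <- !is.na(cn_expr$q_value) & cn_expr$q_value < q_threshold &
    !is.na(cn_expr$r) & cn_expr$r >= r_threshold
  dep_ok <- !is.na(ed$q_value) & ed$q_value < q_threshold &
    !is.na(ed$r) & ed$r <= -r_threshold
  cls <- ifelse(hit & dosage_ok & dep_ok, "expression_biomarker",
                ifelse(hit, "copy_number_only", "inconclusive"))
  data.frame(gene_id = genes,
             r_cn_expr = cn_expr$r, q_cn_expr = cn_expr$q_value,
             r_expr_dep = ed$r, q_expr_dep = ed$q_value,
             screen_hit = hit, classification = cls,
             stringsAsFactors = FALSE)
}
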