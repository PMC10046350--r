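#' Two-tailed pooled-variance Student t-test
#'
#' The screen's per-gene statistic: classic Student t with pooled variance
#' and `n_a + n_b - 2` degrees of freedom, two-tailed. Implemented in closed
#' form so [screen_amplicon()] can evaluate it vectorized across a genome;
#' it agrees with `t.test(..., var.equal = TRUE)` to machine precision. When
#' the pooled variance is exactly zero, equal means give `p = 1` by
#' convention and unequal means are reported as infinitely significant
#' (`t = +/-Inf`, `p = 0`).
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 non-missing
#'   values (`NA`s are dropped).
#' @param welch Use the Welch unequal-variance test instead (off by default;
#'   the screen convention is the pooled Student test).
#' @return A list with `t`, `p`, `df`, `delta` (mean_a - mean_b).
#' @export
student_t_two_tailed <- function(group_a, group_b, welch = FALSE) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  if (welch) {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    return(list(t = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter), delta = mean(a) - mean(b)))
  }
  res <- pooled_t_vec(matrix(c(a, b), nrow = 1L),
                      seq_along(a), length(a) + seq_along(b))
  list(t = res$t[1L], p = res$p[1L], df = res$df[1L], delta = res$delta[1L])
}

# vectorized pooled t over matrix rows; cols_a/cols_b index the two groups.
# NA cells handled per row (listwise within gene). Returns NA-filled rows where
# a group drops below 2 values, and flags zero pooled-variance rows.
pooled_t_vec <- function(values, cols_a, cols_b) {
  va <- values[, cols_a, drop = FALSE]
  vb <- values[, cols_b, drop = FALSE]
  na <- rowSums(!is.na(va))
  nb <- rowSums(!is.na(vb))
  ma <- rowMeans(va, na.rm = TRUE)
  mb <- rowMeans(vb, na.rm = TRUE)
  ssa <- rowSums((va - ma)^2, na.rm = TRUE)
  ssb <- rowSums((vb - mb)^2, na.rm = TRUE)
  df <- na + nb - 2
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  delta <- ma - mb
  t <- delta / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- !is.na(sp2) & sp2 == 0
  t[zero_var & delta == 0] <- 0
  p[zero_var & delta == 0] <- 1
  t[zero_var & delta != 0] <- sign(delta[zero_var & delta != 0]) * Inf
  p[zero_var & delta != 0] <- 0
  usable <- na >= 2 & nb >= 2
  t[!usable] <- NA_real_
  p[!usable] <- NA_real_
  list(t = t, p = p, df = df, delta = delta,
       n_a = na, n_b = nb, mean_a = ma, mean_b = mb,
       zero_variance = zero_var, usable = usable)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjustment `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped at 1,
#' with the input order preserved. Delegates to `stats::p.adjust` after
#' validating the inputs.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return q-values in the same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) {
    stop("p-values outside [0, 1] at position(s): ",
         paste(utils::head(which(!ok), 5L), collapse = ", "), call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Genome-wide differential dependency screen for one amplicon
#'
#' Partitions cell lines into amplified and non-amplified by the call set
#' (the screen convention is the absolute ACN >= 6 partition) and tests every
#' gene's knockout effect between the two groups with a two-tailed pooled
#' Student t-test, followed by Benjamini-Hochberg correction across all
#' tested genes of the screen — the multiple-testing family is genome-wide,
#' not restricted to coamplified genes. Missing effect values are dropped
#' listwise per gene; a gene is skipped (and listed in the `skipped`
#' attribute) when either group falls below 2 values or its effect is
#' constant across all lines.
#'
#' A collateral dependency hit is a gene with `q_value < q_threshold` and
#' `delta < 0` (knockout more deleterious in amplified lines).
#'
#' @param effects A gene-effect [gene_matrix()].
#' @param calls An `amplification_calls` object defining the amplified group.
#' @param amplicon Optional `amplicon` from [find_coamplified()]; sets the
#'   `coamplified` flag.
#' @param cooccurrence Optional data.frame from [cooccurrence_matrix()];
#'   flagged partners of the reference gene are echoed in the
#'   `cooccurrence_note` attribute of the result.
#' @param min_amplified Minimum amplified lines required to run (default 3;
#'   screens with fewer than 5 carry a low-power warning).
#' @return A data.frame (one row per tested gene) with columns `gene_id`,
#'   `n_amplified`, `n_other`, `mean_effect_amplified`, `mean_effect_other`,
#'   `delta`, `t_statistic`, `p_value`, `q_value`, `neg_log10_q`,
#'   `coamplified`, sorted by q then delta. Attributes: `reference_gene`,
#'   `skipped`, `cooccurrence_note`.
#' @export
screen_amplicon <- function(effects, calls, amplicon = NULL,
                            cooccurrence = NULL, min_amplified = 3L) {
  assert_role(effects, "gene_effect")
  amp_samples <- intersect(colnames(effects), calls$amplified_samples)
  other_samples <- setdiff(colnames(effects), calls$amplified_samples)
  if (length(amp_samples) < min_amplified) {
    stop("only ", length(amp_samples), " amplified line(s) with gene-effect ",
         "data for ", calls$reference_gene, "; need >= ", min_amplified,
         call. = FALSE)
  }
  if (length(amp_samples) < 5L) {
    warning("screen for ", calls$reference_gene, " runs on only ",
            length(amp_samples), " amplified lines; expect low power",
            call. = FALSE)
  }
  if (length(other_samples) < 2L) stop("non-amplified group too small", call. = FALSE)

  vals <- unclass(effects)
  res <- pooled_t_vec(vals, match(amp_samples, colnames(effects)),
                      match(other_samples, colnames(effects)))
  constant <- apply(vals, 1L, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0L && all(x == x[1L])
  })
  keep <- res$usable & !constant
  skipped <- data.frame(
    gene_id = rownames(effects)[!keep],
    reason = ifelse(constant[!keep], "constant effect across lines",
                    "group with < 2 non-missing values"),
    stringsAsFactors = FALSE)
  if (nrow(skipped)) {
    message(nrow(skipped), " gene(s) skipped in the ", calls$reference_gene,
            " screen (constant or too sparse)")
  }

  out <- data.frame(
    gene_id = rownames(effects)[keep],
    n_amplified = res$n_a[keep],
    n_other = res$n_b[keep],
    mean_effect_amplified = res$mean_a[keep],
    mean_effect_other = res$mean_b[keep],
    delta = res$delta[keep],
    t_statistic = res$t[keep],
    p_value = res$p[keep],
    stringsAsFactors = FALSE)
  out$q_value <- benjamini_hochberg(out$p_value)
  out$neg_log10_q <- -log10(pmax(out$q_value, 1e-300))
  coamp_genes <- if (is.null(amplicon)) character() else amplicon$coamplified$gene
  out$coamplified <- out$gene_id %in% coamp_genes
  out <- out[order(out$q_value, out$delta, out$gene_id), ]
  rownames(out) <- NULL

  note <- NULL
  if (!is.null(cooccurrence)) {
    hit <- cooccurrence$flagged &
      (cooccurrence$gene_a == calls$reference_gene |
         cooccurrence$gene_b == calls$reference_gene)
    if (any(hit)) {
      partners <- setdiff(unique(c(cooccurrence$gene_a[hit], cooccurrence$gene_b[hit])),
                          calls$reference_gene)
      note <- paste0("high amplification co-occurrence with ",
                     paste(partners, collapse = ", "),
                     "; shared hits may reflect either amplicon")
    }
  }
  structure(out, reference_gene = calls$reference_gene,
            skipped = skipped, cooccurrence_note = note)
}

#' Significant collateral dependencies from a screen
#'
#' @param screen A [screen_amplicon()] result.
#' @param q_threshold FDR bar (default 0.05).
#' @param coamplified_only Restrict to coamplified genes.
#' @return Subset of the screen table with `q_value < q_threshold` and
#'   `delta < 0`.
#' @export
screen_hits <- function(screen, q_threshold = 0.05, coamplified_only = FALSE) {
  hits <- screen[!is.na(screen$q_value) & screen$q_value < q_threshold &
                   screen$delta < 0, , drop = FALSE]
  if (coamplified_only) hits <- hits[hits$coamplified, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Tally significant dependencies across several screens
#'
#' Pools hit rows from per-amplicon screens the way a multi-amplification
#' study reports them: the total counts each (amplicon, gene) hit once, while
#' `n_distinct_genes` collapses genes hit in several screens.
#'
#' @param screens Named list of [screen_amplicon()] results.
#' @param q_threshold FDR bar (default 0.05).
#' @return A list with `n_hits`, `n_distinct_genes`, and the pooled `hits`
#'   table (with an `amplicon` column).
#' @export
tally_screens <- function(screens, q_threshold = 0.05) {
  rows <- lapply(names(screens), function(nm) {
    h <- screen_hits(screens[[nm]], q_threshold)
    if (!nrow(h)) return(NULL)
    cbind(amplicon = nm, h, stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, rows)
  if (is.null(pooled)) pooled <- data.frame()
  list(n_hits = nrow(pooled),
       n_distinct_genes = length(unique(pooled$gene_id)),
       hits = pooled)
}
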