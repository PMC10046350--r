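#' Convert relative to absolute copy number
#'
#' Gene-level copy numbers in DepMap-style exports are stored relative to the
#' cell line's ploidy and log2-transformed with a pseudocount of 1:
#' `RCN = log2(copies / ploidy + 1)`. The absolute copy number is recovered
#' with the ploidy-aware inverse `ACN = ploidy * (2^RCN - 1)`. A stored value
#' of 2 in a diploid line therefore corresponds to 6 copies, the bar used for
#' high-copy amplification calls.
#'
#' @param rcn Relative copy-number value(s), log2(copies/ploidy + 1) scale.
#' @param ploidy Cell-line ploidy (positive; recycled against `rcn`).
#' @return Absolute copy number in copies.
#' @export
rcn_to_acn <- function(rcn, ploidy) {
  if (any(ploidy <= 0, na.rm = TRUE)) stop("ploidy must be positive", call. = FALSE)
  ploidy * (2^rcn - 1)
}

#' @rdname rcn_to_acn
#' @param acn Absolute copy number (non-negative copies).
#' @return `acn_to_rcn()` returns the stored relative copy-number value.
#' @export
acn_to_rcn <- function(acn, ploidy) {
  if (any(ploidy <= 0, na.rm = TRUE)) stop("ploidy must be positive", call. = FALSE)
  if (any(acn < 0, na.rm = TRUE)) stop("absolute copy number must be non-negative", call. = FALSE)
  log2(acn / ploidy + 1)
}

#' Call high-copy amplifications at one gene
#'
#' A sample is called amplified either in `relative` mode (stored RCN >= 2,
#' the threshold used for tumor/cell-line frequency maps) or in `absolute`
#' mode (ACN >= 6 copies, the partition used by the dependency screen). For
#' diploid samples the two rules coincide; for other ploidies the calls can
#' differ, and any disagreement is reported in the `mode_discrepancy`
#' attribute.
#'
#' @param rcn A copy-number [gene_matrix()].
#' @param samples Sample table (see [read_sample_table()]); samples absent
#'   from it are assumed diploid.
#' @param gene Reference gene symbol.
#' @param mode `"relative"` (RCN >= `rcn_threshold`) or `"absolute"`
#'   (ACN >= `acn_threshold`).
#' @param rcn_threshold,acn_threshold Call thresholds; defaults 2 and 6.
#' @return An `amplification_calls` object: list with `reference_gene`,
#'   `threshold_mode`, `amplified_samples`, and per-sample `acn` at the gene.
#'   Samples with a missing copy-number value are never called.
#' @export
call_amplifications <- function(rcn, samples = NULL, gene,
                                mode = c("relative", "absolute"),
                                rcn_threshold = 2, acn_threshold = 6) {
  assert_role(rcn, "copy_number")
  mode <- match.arg(mode)
  if (!gene %in% rownames(rcn)) {
    stop("gene '", gene, "' absent from the copy-number matrix; ",
         "if it lacks copy-number data, map it to a neighboring surrogate ",
         "(see resolve_surrogates())", call. = FALSE)
  }
  vals <- rcn[gene, ]
  ploidy <- rep(2, ncol(rcn))
  names(ploidy) <- colnames(rcn)
  if (!is.null(samples)) {
    idx <- match(colnames(rcn), samples$sample_id)
    ploidy[!is.na(idx)] <- samples$ploidy[idx[!is.na(idx)]]
  }
  acn <- rcn_to_acn(vals, ploidy)
  rel_call <- !is.na(vals) & vals >= rcn_threshold
  abs_call <- !is.na(acn) & acn >= acn_threshold
  called <- if (mode == "relative") rel_call else abs_call
  discrepant <- colnames(rcn)[rel_call != abs_call]
  structure(
    list(reference_gene = gene,
         threshold_mode = mode,
         amplified_samples = colnames(rcn)[called],
         acn = acn,
         mode_discrepancy = discrepant),
    class = "amplification_calls")
}

#' @export
print.amplification_calls <- function(x, ...) {
  cat(sprintf("<amplification_calls %s [%s]: %d/%d samples amplified>\n",
              x$reference_gene, x$threshold_mode,
              length(x$amplified_samples), length(x$acn)))
  invisible(x)
}

#' Build a coamplicon around a reference gene
#'
#' Coamplified genes are found by correlating the reference gene's stored
#' copy-number profile against every other gene's across all samples
#' (Pearson, pairwise-complete). Genes at or above `r_threshold` — applied to
#' the signed r, so anti-correlated genes never qualify — form the amplicon,
#' with the reference itself included at r = 1.
#'
#' @param rcn A copy-number [gene_matrix()].
#' @param reference_gene Reference gene symbol.
#' @param r_threshold Minimum Pearson r to call a gene coamplified (default 0.7).
#' @param min_pairs Minimum complete observation pairs per candidate (default 3).
#' @param band Optional chromosomal band label for the amplicon.
#' @return An `amplicon` object: list with `reference_gene`, `band`,
#'   `r_threshold`, and `coamplified`, a data.frame of member genes and their r.
#' @export
find_coamplified <- function(rcn, reference_gene, r_threshold = 0.7,
                             min_pairs = 3, band = NULL) {
  assert_role(rcn, "copy_number")
  if (!reference_gene %in% rownames(rcn)) {
    stop("reference gene '", reference_gene, "' absent from matrix", call. = FALSE)
  }
  ref <- rcn[reference_gene, ]
  if (sum(!is.na(ref)) < min_pairs || stats::sd(ref, na.rm = TRUE) == 0) {
    stop("reference copy-number vector has no variation; correlation undefined",
         call. = FALSE)
  }
  r <- suppressWarnings(
    stats::cor(ref, t(unclass(rcn)), use = "pairwise.complete.obs")[1L, ])
  n_pairs <- colSums(!is.na(t(unclass(rcn))) & !is.na(ref))
  r[n_pairs < min_pairs] <- NA_real_
  r[reference_gene] <- 1
  keep <- !is.na(r) & r >= r_threshold
  members <- data.frame(gene = names(r)[keep], r = unname(r[keep]),
                        stringsAsFactors = FALSE)
  members <- members[order(-members$r, members$gene), ]
  rownames(members) <- NULL
  structure(
    list(reference_gene = reference_gene, band = band,
         r_threshold = r_threshold, coamplified = members),
    class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon %s%s: %d coamplified genes at r >= %g>\n",
              x$reference_gene,
              if (is.null(x$band)) "" else paste0(" (", x$band, ")"),
              nrow(x$coamplified), x$r_threshold))
  invisible(x)
}

#' Amplification frequency per lineage
#'
#' Frequency = amplified samples / group size, computed per lineage (or any
#' other grouping column of the sample table). Lineages with no samples
#' carrying a copy-number value are dropped with a warning.
#'
#' @param calls An `amplification_calls` object (or list of them).
#' @param samples Sample table.
#' @param by Grouping column of `samples`; default `"lineage"`.
#' @return A data.frame with columns `reference_gene`, group, `n`,
#'   `n_amplified`, `frequency`.
#' @export
amplification_frequency <- function(calls, samples, by = "lineage") {
  if (inherits(calls, "amplification_calls")) calls <- list(calls)
  if (!by %in% colnames(samples)) stop("no column '", by, "' in sample table", call. = FALSE)
  out <- lapply(calls, function(cs) {
    measured <- names(cs$acn)[!is.na(cs$acn)]
    tab <- samples[samples$sample_id %in% measured, , drop = FALSE]
    if (!nrow(tab)) {
      warning("no measured samples for ", cs$reference_gene, call. = FALSE)
      return(NULL)
    }
    groups <- split(tab$sample_id, tab[[by]])
    data.frame(
      reference_gene = cs$reference_gene,
      group = names(groups),
      n = lengths(groups),
      n_amplified = vapply(groups, function(g) sum(g %in% cs$amplified_samples), 0L),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$frequency <- res$n_amplified / res$n
  names(res)[names(res) == "group"] <- by
  rownames(res) <- NULL
  res
}

similarity_tier <- function(r) {
  if (is.na(r)) "not_evaluable"
  else if (r >= 0.7) "high"
  else if (r >= 0.4) "moderate"
  else "weak"
}

#' Tumor vs cell-line amplification-frequency similarity
#'
#' For each lineage, Pearson-correlates the amplification frequencies of the
#' reference genes observed in tumors against those observed in cell lines,
#' and tiers the agreement: high (r >= 0.7), moderate (0.4 <= r < 0.7), weak
#' (r < 0.4). Lineages where either frequency vector is degenerate (fewer
#' than 3 reference genes, or zero variance — typically lineages where
#' amplification is rare) are reported `not_evaluable`.
#'
#' @param tumor_freqs,cellline_freqs Frequency tables from
#'   [amplification_frequency()] (columns `reference_gene`, `lineage`,
#'   `frequency`), one computed on tumors and one on cell lines.
#' @return A data.frame with one row per shared lineage: `lineage`, `n_genes`,
#'   `r`, `tier`.
#' @export
lineage_similarity <- function(tumor_freqs, cellline_freqs) {
  lineages <- intersect(unique(tumor_freqs$lineage), unique(cellline_freqs$lineage))
  if (!length(lineages)) stop("no shared lineages between the two frequency tables", call. = FALSE)
  rows <- lapply(lineages, function(lin) {
    tf <- tumor_freqs[tumor_freqs$lineage == lin, ]
    cf <- cellline_freqs[cellline_freqs$lineage == lin, ]
    genes <- intersect(tf$reference_gene, cf$reference_gene)
    x <- tf$frequency[match(genes, tf$reference_gene)]
    y <- cf$frequency[match(genes, cf$reference_gene)]
    r <- if (length(genes) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      NA_real_
    } else {
      stats::cor(x, y)
    }
    data.frame(lineage = lin, n_genes = length(genes), r = r,
               tier = similarity_tier(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pairwise amplification co-occurrence
#'
#' Reference genes on adjacent chromosomal bands (e.g. CDK4 and MDM2 on
#' 12q14/12q15) tend to be amplified in overlapping sets of lines, which can
#' make their screens share hits. This quantifies the overlap for every pair
#' of call sets: Jaccard index and the two conditional frequencies
#' P(A amplified | B amplified) and vice versa, with pairs above
#' `flag_threshold` (Jaccard) flagged for annotation downstream.
#'
#' @param call_sets List of `amplification_calls` objects (>= 2).
#' @param flag_threshold Jaccard index above which a pair is flagged; default 0.5.
#' @return A data.frame with one row per unordered pair: `gene_a`, `gene_b`,
#'   `n_a`, `n_b`, `n_both`, `jaccard`, `p_a_given_b`, `p_b_given_a`, `flagged`.
#' @export
cooccurrence_matrix <- function(call_sets, flag_threshold = 0.5) {
  if (length(call_sets) < 2L) stop("need at least two call sets", call. = FALSE)
  genes <- vapply(call_sets, function(x) x$reference_gene, "")
  pairs <- utils::combn(seq_along(call_sets), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    a <- call_sets[[ij[1L]]]$amplified_samples
    b <- call_sets[[ij[2L]]]$amplified_samples
    both <- length(intersect(a, b))
    uni <- length(union(a, b))
    data.frame(
      gene_a = genes[ij[1L]], gene_b = genes[ij[2L]],
      n_a = length(a), n_b = length(b), n_both = both,
      jaccard = if (uni == 0L) 0 else both / uni,
      p_a_given_b = if (length(b)) both / length(b) else NA_real_,
      p_b_given_a = if (length(a)) both / length(a) else NA_real_,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$flagged <- res$jaccard >= flag_threshold
  rownames(res) <- NULL
  res
}
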