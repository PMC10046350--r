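#' Prioritize screen hits by accessibility and ligandability
#'
#' Codifies the druggability triage applied to significant collateral
#' dependencies: proteins secreted or sitting in the cell membrane (tier 1)
#' are more accessible to small molecules and antibodies than those in the
#' cytoplasm, nucleus or organelles (tier 2), for which the structure-based
#' ligandability score (-3 low to 3 high) carries the weight. Within a tier,
#' hits sort by q-value ascending, then ligandability descending (missing
#' scores last), then gene id — a total deterministic order. Hits with a
#' ligandability score >= 0 get a `druggable` badge; the badge never affects
#' the rank. Hits lacking an annotation fall to tier 2 with localization
#' `unknown` and are listed in the `unannotated` attribute.
#'
#' @param hits Screen hits (rows of a [screen_amplicon()] table with
#'   `q_value < 0.05` and `delta < 0`; enforce with [screen_hits()]).
#' @param annotations Annotation table from [read_target_annotations()].
#' @param amplicon_label Label recorded in the output's `amplicon` column.
#' @return A data.frame ranked best-first: `rank`, `gene_id`, `amplicon`,
#'   `q_value`, `delta`, `localization`, `ligandability`, `tier`, `druggable`.
#' @export
prioritize_targets <- function(hits, annotations, amplicon_label = NA_character_) {
  bad <- !is.na(hits$q_value) & (hits$q_value >= 0.05 | hits$delta >= 0)
  if (any(bad)) {
    stop("prioritization input must be significant dependencies ",
         "(q < 0.05 and delta < 0); offending gene(s): ",
         paste(utils::head(hits$gene_id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  idx <- match(hits$gene_id, annotations$gene_id)
  loc <- ifelse(is.na(idx), "unknown", annotations$localization[idx])
  lig <- ifelse(is.na(idx), NA_real_, annotations$ligandability[idx])
  unannotated <- hits$gene_id[is.na(idx)]
  if (length(unannotated)) {
    message(length(unannotated), " hit(s) lack annotations; assigned tier 2 / unknown: ",
            paste(utils::head(unannotated, 5L), collapse = ", "))
  }
  tier <- ifelse(loc %in% c("membrane", "secreted"), 1L, 2L)
  # missing ligandability sorts last within a tier/q stratum
  lig_key <- ifelse(is.na(lig), -Inf, lig)
  ord <- order(tier, hits$q_value, -lig_key, hits$gene_id)
  out <- data.frame(
    rank = seq_along(ord),
    gene_id = hits$gene_id[ord],
    amplicon = amplicon_label,
    q_value = hits$q_value[ord],
    delta = hits$delta[ord],
    localization = loc[ord],
    ligandability = lig[ord],
    tier = tier[ord],
    stringsAsFactors = FALSE)
  out$druggable <- !is.na(out$ligandability) & out$ligandability >= 0
  structure(out, unannotated = unannotated)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p < 1e-4, "****",
                ifelse(p < 1e-3, "***",
                       ifelse(p < 0.01, "**",
                              ifelse(p < 0.05, "*", "ns")))))
}

#' Per-lineage confirmation of a prioritized dependency
#'
#' Re-tests a gene's knockout-effect difference between amplified and
#' non-amplified cell lines inside each selected lineage with the two-tailed
#' pooled Student t-test. p-values are reported uncorrected (the confirmation
#' step applies no multiplicity correction) and star-coded at
#' 0.05/0.01/0.001/0.0001. Lineages with fewer than 2 amplified or 2
#' non-amplified lines are reported `ns — underpowered` without a test.
#'
#' @param effects A gene-effect [gene_matrix()].
#' @param calls An `amplification_calls` object.
#' @param gene Gene whose effect is compared.
#' @param samples Sample table (for the lineage of each line).
#' @param lineages Lineages to test; default all in `samples`.
#' @return A data.frame per lineage: `lineage`, `n_amplified`, `n_other`,
#'   `delta`, `t_statistic`, `p_value`, `stars`, `note`.
#' @export
lineage_confirmation <- function(effects, calls, gene, samples,
                                 lineages = unique(samples$lineage)) {
  assert_role(effects, "gene_effect")
  if (!gene %in% rownames(effects)) stop("gene '", gene, "' has no effect data", call. = FALSE)
  rows <- lapply(lineages, function(lin) {
    ids <- intersect(samples$sample_id[samples$lineage == lin], colnames(effects))
    amp <- intersect(ids, calls$amplified_samples)
    oth <- setdiff(ids, calls$amplified_samples)
    vals_a <- effects[gene, amp]
    vals_o <- effects[gene, oth]
    if (sum(!is.na(vals_a)) < 2L || sum(!is.na(vals_o)) < 2L) {
      return(data.frame(lineage = lin, n_amplified = length(amp),
                        n_other = length(oth), delta = NA_real_,
                        t_statistic = NA_real_, p_value = NA_real_,
                        stars = "ns", note = "underpowered",
                        stringsAsFactors = FALSE))
    }
    tt <- student_t_two_tailed(vals_a, vals_o)
    data.frame(lineage = lin, n_amplified = length(amp), n_other = length(oth),
               delta = tt$delta, t_statistic = tt$t, p_value = tt$p,
               stars = significance_stars(tt$p), note = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Resolve the copy-number gene standing in for a target
#'
#' Some targets lack their own copy-number row (the exports simply omit
#' them); amplification status is then read from a closely located surrogate
#' gene — e.g. a neighboring gene or the coamplified pseudogene that gave
#' rise to the hit. A gene with its own copy-number row and no map entry
#' resolves to itself; a mapped gene resolves to its surrogate (which must be
#' present in the matrix); anything else is an error naming both lookups.
#'
#' @param surrogate_map Named character vector or list, `target -> surrogate`.
#' @param gene Target gene.
#' @param rcn The copy-number [gene_matrix()].
#' @return The effective copy-number gene, with attribute `via_surrogate`.
#' @export
resolve_surrogates <- function(surrogate_map, gene, rcn) {
  assert_role(rcn, "copy_number")
  mapped <- if (gene %in% names(surrogate_map)) surrogate_map[[gene]] else NULL
  if (!is.null(mapped)) {
    if (!mapped %in% rownames(rcn)) {
      stop("surrogate '", mapped, "' for '", gene,
           "' absent from the copy-number matrix", call. = FALSE)
    }
    return(structure(mapped, via_surrogate = TRUE))
  }
  if (gene %in% rownames(rcn)) return(structure(gene, via_surrogate = FALSE))
  stop("no copy-number data for '", gene,
       "' and no surrogate mapping; looked up '", gene,
       "' in both the surrogate map and the matrix rows", call. = FALSE)
}
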