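#' Hypergeometric overlap of a query with one gene set
#'
#' Upper-tail hypergeometric test of the overlap between a query (e.g. the
#' significant dependencies of a screen) and a target set (e.g. one
#' chromosome-band positional set), within a stated universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where `N` is the
#' universe size, `K` the target size, `n` the query size and `k` the
#' observed overlap.
#'
#' @param query,target Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector of gene ids defining the draw population.
#' @return A list with `k`, `K`, `n`, `N`, `gene_ratio` (k/K), `p_value`,
#'   and `overlap_genes`.
#' @export
hypergeom_overlap <- function(query, target, universe) {
  query <- unique(query); target <- unique(target); universe <- unique(universe)
  stray_q <- setdiff(query, universe)
  if (length(stray_q)) {
    stop("query genes outside the universe: ",
         paste(utils::head(stray_q, 5L), collapse = ", "), call. = FALSE)
  }
  stray_t <- setdiff(target, universe)
  if (length(stray_t)) {
    stop("target genes outside the universe: ",
         paste(utils::head(stray_t, 5L), collapse = ", "), call. = FALSE)
  }
  overlap <- intersect(query, target)
  k <- length(overlap); K <- length(target); n <- length(query); N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N,
       gene_ratio = if (K > 0L) k / K else NA_real_,
       p_value = p, overlap_genes = overlap)
}

#' Positional overlap analysis across a gene-set collection
#'
#' Tests every set of the collection against the query with
#' [hypergeom_overlap()] and corrects across sets with Benjamini-Hochberg.
#' The default universe is the intersection of the screen's tested genes
#' with the collection's genes (sets are truncated to the universe);
#' passing `universe = NULL` with `collection_universe = TRUE` uses all
#' collection genes instead.
#'
#' @param query Character vector of significant genes.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of tested genes (e.g. the screen's
#'   `gene_id` column); intersected with the collection genes unless
#'   `collection_universe`.
#' @param collection_universe If `TRUE`, the universe is the union of all
#'   collection genes regardless of `universe`.
#' @return A data.frame with one row per set — `set_name`, `K`, `k`,
#'   `gene_ratio`, `p_value`, `q_value`, `N`, `n` — sorted by q then
#'   gene_ratio descending. Empty queries return an empty table with a
#'   warning.
#' @export
overlap_analysis <- function(query, collection, universe,
                             collection_universe = FALSE) {
  all_set_genes <- unique(unlist(collection, use.names = FALSE))
  uni <- if (collection_universe) all_set_genes else intersect(universe, all_set_genes)
  query <- intersect(unique(query), uni)
  if (!length(query)) {
    warning("no query genes inside the universe; empty overlap table", call. = FALSE)
    return(data.frame(set_name = character(), K = integer(), k = integer(),
                      gene_ratio = numeric(), p_value = numeric(),
                      q_value = numeric(), N = integer(), n = integer()))
  }
  rows <- lapply(names(collection), function(nm) {
    target <- intersect(collection[[nm]], uni)
    if (!length(target)) return(NULL)
    ov <- hypergeom_overlap(query, target, uni)
    data.frame(set_name = nm, K = ov$K, k = ov$k, gene_ratio = ov$gene_ratio,
               p_value = ov$p_value, N = ov$N, n = ov$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- benjamini_hochberg(res$p_value)
  res <- res[order(res$q_value, -res$gene_ratio, res$set_name),
             c("set_name", "K", "k", "gene_ratio", "p_value", "q_value", "N", "n")]
  rownames(res) <- NULL
  res
}

#' Build the preranked list for GSEA from a screen table
#'
#' The screen orders genes by FDR q-value; because q alone is unsigned, the
#' rank score makes the direction explicit:
#' `score = -log10(max(q, 1e-300)) * sign(-delta)`, so the strongest
#' dependencies (small q, negative delta) head the list and
#' amplification-protective genes (delta > 0) sink to the bottom. Ties are
#' broken by p-value, then |delta| (larger first), then gene id, giving a
#' total deterministic order.
#'
#' @param screen A [screen_amplicon()] result.
#' @return A data.frame `gene_id`, `score` in rank order (best first).
#' @export
rank_for_gsea <- function(screen) {
  score <- -log10(pmax(screen$q_value, 1e-300)) * sign(-screen$delta)
  ord <- order(-score, screen$p_value, -abs(screen$delta), screen$gene_id)
  out <- data.frame(gene_id = screen$gene_id[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov-style running sum. scores are in rank order;
# hit_pos are positions of the target genes. Hit steps are |score|^weight
# normalized to sum 1; miss steps are 1/(N - n_hits). ES is the deviation of
# largest magnitude (ties resolved toward the positive extreme). Only values
# at/adjacent to hit positions need inspecting: between hits the sum decays
# linearly, so the running maximum is at a hit and the minimum just before one
# (or at the final miss).
gsea_es <- function(scores, hit_pos, weight = 1) {
  N <- length(scores)
  m <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs(scores[hit_pos])^weight
  sw <- sum(w)
  w <- if (sw == 0) rep(1 / m, m) else w / sw
  miss_step <- 1 / (N - m)
  cum_hit <- cumsum(w)
  after <- cum_hit - (hit_pos - seq_len(m)) * miss_step       # just after hit j
  before <- c(0, cum_hit[-m]) - (hit_pos - seq_len(m)) * miss_step  # just before hit j
  hi <- max(after)
  lo <- min(c(before, cum_hit[m] - (N - m) * miss_step))      # end of list = 0 check
  # near-exact magnitude ties (possible at weight 0) resolve to the positive
  # deviation, within floating tolerance
  if (hi >= -lo - 1e-9) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Weighted running-sum enrichment of one target set in a ranked, scored gene
#' list, as used to confirm that coamplified genes concentrate among the top
#' dependencies of a screen. Hits advance the running sum by their
#' `|score|^weight` (normalized over the set); misses retreat it by
#' `1/(N - N_hit)`; the enrichment score ES is the deviation of largest
#' magnitude. The null distribution comes from random gene sets of the same
#' size drawn from the ranked list (gene-label permutation, the standard for
#' preranked mode). NES divides ES by the mean of the same-sign permutation
#' scores ("meandiv" normalization); the nominal p is the same-sign
#' permutation tail fraction; the FDR q compares the observed |NES| against
#' the pool of same-sign permutation NES.
#'
#' @param ranked A data.frame from [rank_for_gsea()] (columns `gene_id`,
#'   `score`, best first).
#' @param target Character vector of gene ids; must intersect the ranked list
#'   and be a proper subset of it.
#' @param n_perm Number of permutations (default 10000).
#' @param weight Exponent of the weighted statistic (default 1).
#' @param seed Integer seed making the permutation null reproducible.
#' @param set_name Label carried into the result.
#' @return A list of class `gsea_result`: `set_name`, `es`, `nes`,
#'   `nominal_p`, `fdr_q`, `n_permutations`, `n_hits`, `leading_edge`.
#' @export
preranked_gsea <- function(ranked, target, n_perm = 10000L, weight = 1,
                           seed = 1L, set_name = "target") {
  stopifnot(is.data.frame(ranked), all(c("gene_id", "score") %in% colnames(ranked)))
  hit_pos <- which(ranked$gene_id %in% target)
  N <- nrow(ranked)
  if (!length(hit_pos)) stop("target set does not intersect the ranked list", call. = FALSE)
  if (length(hit_pos) == N) stop("target set equals the entire ranked list", call. = FALSE)
  scores <- ranked$score
  m <- length(hit_pos)

  es <- gsea_es(scores, hit_pos, weight)

  set.seed(seed)
  perm_es <- vapply(seq_len(n_perm), function(i) {
    gsea_es(scores, sample.int(N, m), weight)
  }, 0)

  same_sign <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
  mean_same <- mean(abs(same_sign))
  nes <- if (length(same_sign) && mean_same > 0) es / mean_same else NA_real_
  nominal_p <- if (length(same_sign)) {
    sum(abs(same_sign) >= abs(es)) / length(same_sign)
  } else NA_real_
  # single-set FDR: share of same-sign permutation NES at least as extreme
  # as the observed NES (the observed-side ratio is 1 with one set)
  fdr_q <- if (!is.na(nes) && length(same_sign)) {
    perm_nes <- abs(same_sign) / mean_same
    min(1, sum(perm_nes >= abs(nes)) / length(perm_nes))
  } else NA_real_

  # leading edge: hits at or before the ES extremum (after it for negative ES)
  le <- leading_edge_genes(ranked, hit_pos, weight, es)
  structure(list(set_name = set_name, es = es, nes = nes,
                 nominal_p = nominal_p, fdr_q = fdr_q,
                 n_permutations = n_perm, n_hits = m,
                 leading_edge = le),
            class = "gsea_result")
}

leading_edge_genes <- function(ranked, hit_pos, weight, es) {
  N <- nrow(ranked)
  m <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs(ranked$score[hit_pos])^weight
  if (sum(w) == 0) w <- rep(1 / m, m) else w <- w / sum(w)
  miss_step <- 1 / (N - m)
  after <- cumsum(w) - (hit_pos - seq_len(m)) * miss_step
  if (es >= 0) {
    peak <- which.max(after)
    ranked$gene_id[hit_pos[seq_len(peak)]]
  } else {
    before <- c(0, cumsum(w)[-m]) - (hit_pos - seq_len(m)) * miss_step
    trough <- which.min(before)
    ranked$gene_id[hit_pos[hit_pos >= hit_pos[trough]]]
  }
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea %s: ES=%.3f NES=%.3f p=%.4g FDR=%.4g (%d hits, %d perms)>\n",
              x$set_name, x$es, x$nes, x$nominal_p, x$fdr_q,
              x$n_hits, x$n_permutations))
  invisible(x)
}
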