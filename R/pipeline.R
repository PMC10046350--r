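#' Assemble a pipeline configuration
#'
#' Gathers input locations, the amplicon registry and every analysis
#' threshold into one validated object. Threshold defaults are the study
#' conventions used throughout the package: coamplification at r >= 0.7,
#' amplification calls at RCN >= 2 (relative) with the screen partition at
#' ACN >= 6 copies (absolute), significance at q < 0.05, similarity tiers at
#' 0.4/0.7, and GSEA with 10,000 permutations of the weighted (exponent 1)
#' statistic.
#'
#' @param inputs Named list of paths: `copy_number`, `gene_effect`,
#'   `samples` required; `expression`, `survival`, `positional_sets`,
#'   `annotations` optional (stages needing an absent input are skipped).
#' @param registry List of amplicons, each a list with `gene` (reference
#'   gene), optional `band` label and optional `surrogate` (copy-number
#'   stand-in for a target without its own row).
#' @param r_threshold,rcn_threshold,acn_threshold,q_threshold,similarity_tiers
#'   Analysis thresholds (defaults as above).
#' @param gsea_perms,gsea_weight Preranked GSEA settings.
#' @param min_amplified Minimum amplified lines to run a screen.
#' @param lineages Optional lineage subset for confirmation/biomarker stages;
#'   default all lineages in the sample table.
#' @param seed Seed for every stochastic stage (GSEA permutations).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = list(), registry = list(),
                            r_threshold = 0.7, rcn_threshold = 2,
                            acn_threshold = 6, q_threshold = 0.05,
                            similarity_tiers = c(0.4, 0.7),
                            gsea_perms = 10000L, gsea_weight = 1,
                            min_amplified = 3L, lineages = NULL,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (length(registry)) {
    for (entry in registry) {
      if (is.null(entry$gene)) stop("every registry entry needs a `gene`", call. = FALSE)
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

pipeline_log <- function(state, ...) {
  line <- paste0(...)
  message(line)
  state$log <- c(state$log, line)
  state
}

#' Run the full amplification-dependency pipeline
#'
#' Orchestrates every stage end-to-end: amplification calls -> coamplicon
#' construction -> co-occurrence -> genome-wide dependency screens ->
#' positional overlap and preranked GSEA -> target prioritization ->
#' expression-biomarker assessment -> survival comparisons -> summary. Each
#' stage writes a TSV into `out_dir`; a machine-readable `summary.json`, the
#' config echo (`config_used.yaml`) and a plain `run.log` accompany them.
#' Outputs are pure functions of inputs + config, so a rerun with the same
#' seed is byte-identical. Stages whose inputs are absent are skipped with a
#' logged notice; a stage precondition failure halts with the stage name.
#'
#' @param config A [pipeline_config()] (or path to its YAML form).
#' @param out_dir Output directory, created if needed.
#' @param bundle Optional in-memory bundle (as from [simulate_bundle()]);
#'   when given, its objects take the place of the configured input paths.
#' @return Invisibly, a list with every stage's result plus `summary`.
#' @export
run_pipeline <- function(config, out_dir, bundle = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  state <- list(log = character())

  ## ---- load inputs ----
  if (!is.null(bundle)) {
    rcn <- bundle$rcn; effects <- bundle$effects
    expression <- bundle$expression; samples <- bundle$samples
    surv <- bundle$survival; psets <- bundle$positional_sets
    annotations <- bundle$annotations
    if (!length(config$registry)) {
      config$registry <- list(list(gene = bundle$truth$reference_gene,
                                   band = bundle$truth$band))
    }
  } else {
    need <- c("copy_number", "gene_effect", "samples")
    missing_in <- setdiff(need, names(config$inputs))
    if (length(missing_in)) {
      stop("stage load: required input(s) missing from config: ",
           paste(missing_in, collapse = ", "), call. = FALSE)
    }
    rcn <- read_gene_matrix(config$inputs$copy_number, "copy_number")
    effects <- read_gene_matrix(config$inputs$gene_effect, "gene_effect")
    samples <- read_sample_table(config$inputs$samples)
    expression <- if (!is.null(config$inputs$expression)) {
      read_gene_matrix(config$inputs$expression, "expression")
    }
    surv <- if (!is.null(config$inputs$survival)) {
      data.table::fread(config$inputs$survival, sep = "\t", header = TRUE,
                        data.table = FALSE)
    }
    psets <- if (!is.null(config$inputs$positional_sets)) {
      read_gmt(config$inputs$positional_sets)
    }
    annotations <- if (!is.null(config$inputs$annotations)) {
      read_target_annotations(config$inputs$annotations)
    }
  }
  if (!length(config$registry)) stop("stage load: empty amplicon registry", call. = FALSE)
  state <- pipeline_log(state, "loaded ", nrow(rcn), " genes x ", ncol(rcn),
                        " samples; registry of ", length(config$registry),
                        " amplicon(s)")

  results <- list()
  calls_abs <- list()

  ## ---- per-amplicon: calls, coamplicon ----
  for (entry in config$registry) {
    gene <- entry$gene
    cn_gene <- if (!is.null(entry$surrogate)) entry$surrogate else gene
    calls <- call_amplifications(rcn, samples, cn_gene, mode = "absolute",
                                 rcn_threshold = config$rcn_threshold,
                                 acn_threshold = config$acn_threshold)
    if (length(calls$mode_discrepancy)) {
      state <- pipeline_log(state, gene, ": relative/absolute call modes disagree for ",
                            length(calls$mode_discrepancy), " non-diploid line(s)")
    }
    amplicon <- find_coamplified(rcn, cn_gene, r_threshold = config$r_threshold,
                                 band = entry$band)
    calls_abs[[gene]] <- calls
    results[[gene]] <- list(calls = calls, amplicon = amplicon, entry = entry)
    state <- pipeline_log(state, gene, ": ", length(calls$amplified_samples),
                          " amplified lines, ", nrow(amplicon$coamplified),
                          " coamplified genes")
  }

  ## ---- co-occurrence ----
  cooc <- NULL
  if (length(calls_abs) >= 2L) {
    cooc <- cooccurrence_matrix(calls_abs)
    write_results_table(cooc, file.path(out_dir, "cooccurrence.tsv"))
    state <- pipeline_log(state, "co-occurrence: ", sum(cooc$flagged), " flagged pair(s)")
  }

  ## ---- screens + enrichment + prioritization + biomarker ----
  summary_amp <- list()
  for (gene in names(results)) {
    res <- results[[gene]]
    screen <- screen_amplicon(effects, res$calls, res$amplicon,
                              cooccurrence = cooc,
                              min_amplified = config$min_amplified)
    hits <- screen_hits(screen, config$q_threshold)
    write_results_table(screen, file.path(out_dir, paste0("screen_", gene, ".tsv")))
    state <- pipeline_log(state, gene, ": screen tested ", nrow(screen),
                          " genes, ", nrow(hits), " significant dependencies (",
                          sum(hits$coamplified), " coamplified)")

    overlap <- NULL
    if (!is.null(psets) && nrow(hits)) {
      overlap <- overlap_analysis(hits$gene_id, psets, screen$gene_id)
      write_results_table(overlap, file.path(out_dir, paste0("overlap_", gene, ".tsv")))
    }

    gsea <- NULL
    coamp_set <- setdiff(res$amplicon$coamplified$gene, res$amplicon$reference_gene)
    coamp_set <- intersect(coamp_set, screen$gene_id)
    if (length(coamp_set) && length(coamp_set) < nrow(screen)) {
      ranked <- rank_for_gsea(screen)
      gsea <- preranked_gsea(ranked, coamp_set, n_perm = config$gsea_perms,
                             weight = config$gsea_weight, seed = config$seed,
                             set_name = paste0(gene, "_coamplified"))
      state <- pipeline_log(state, gene, sprintf(": GSEA NES=%.3f FDR=%.4g",
                                                 gsea$nes, gsea$fdr_q))
    }

    prioritized <- NULL
    if (!is.null(annotations) && nrow(hits)) {
      prioritized <- prioritize_targets(hits, annotations, amplicon_label = gene)
      write_results_table(prioritized, file.path(out_dir, paste0("prioritized_", gene, ".tsv")))
    }

    biomarker <- NULL
    if (!is.null(expression) && !is.null(prioritized) && nrow(prioritized)) {
      scope <- if (is.null(config$lineages)) NULL else {
        samples$sample_id[samples$lineage %in% config$lineages]
      }
      surro <- list()
      if (!is.null(res$entry$surrogate)) surro[[gene]] <- res$entry$surrogate
      ce <- cn_expression_correlation(rcn, expression, prioritized$gene_id,
                                      sample_ids = scope, surrogate_map = surro)
      ed <- expression_dependency_correlation(expression, effects,
                                              prioritized$gene_id,
                                              sample_ids = scope)
      biomarker <- classify_biomarker(ce, ed, prioritized$gene_id,
                                      q_threshold = config$q_threshold)
      write_results_table(biomarker, file.path(out_dir, paste0("biomarker_", gene, ".tsv")))
    } else if (is.null(expression)) {
      state <- pipeline_log(state, gene, ": expression input absent; biomarker stage skipped")
    }

    results[[gene]]$screen <- screen
    results[[gene]]$hits <- hits
    results[[gene]]$overlap <- overlap
    results[[gene]]$gsea <- gsea
    results[[gene]]$prioritized <- prioritized
    results[[gene]]$biomarker <- biomarker

    summary_amp[[gene]] <- list(
      reference_gene = gene,
      n_amplified = length(res$calls$amplified_samples),
      n_coamplified = nrow(res$amplicon$coamplified),
      coamplified_genes = res$amplicon$coamplified$gene,
      n_tested = nrow(screen),
      n_hits = nrow(hits),
      dependent_genes = hits$gene_id[hits$coamplified],
      top_overlap_set = if (!is.null(overlap) && nrow(overlap)) overlap$set_name[1L] else NULL,
      top_overlap_q = if (!is.null(overlap) && nrow(overlap)) overlap$q_value[1L] else NULL,
      gsea_nes = if (!is.null(gsea)) gsea$nes else NULL,
      gsea_fdr = if (!is.null(gsea)) gsea$fdr_q else NULL,
      top_prioritized = if (!is.null(prioritized)) utils::head(prioritized$gene_id, 5L) else NULL,
      expression_biomarkers = if (!is.null(biomarker)) {
        biomarker$gene_id[biomarker$classification == "expression_biomarker"]
      } else NULL)
  }

  ## ---- survival ----
  surv_cmp <- NULL
  if (!is.null(surv)) {
    amp_sets <- if (!is.null(bundle) && !is.null(bundle$truth$amplified_tumors)) {
      # tumor cohort: membership comes from the tumor table, not cell-line calls
      stats::setNames(list(bundle$truth$amplified_tumors),
                      names(calls_abs)[1L])
    } else {
      lapply(calls_abs, `[[`, "amplified_samples")
    }
    surv_cmp <- compare_survival(surv, amp_sets)
    if (is.null(surv_cmp) || !nrow(surv_cmp)) {
      surv_cmp <- NULL
      state <- pipeline_log(state, "survival: no resolvable comparisons ",
                            "(no overlap between amplified sets and survival ids)")
    } else {
      write_results_table(surv_cmp, file.path(out_dir, "survival_comparisons.tsv"))
      state <- pipeline_log(state, "survival: ", nrow(surv_cmp), " comparison(s)")
    }
  } else {
    state <- pipeline_log(state, "survival input absent; survival stage skipped")
  }

  ## ---- summary + echo ----
  summary <- list(
    seed = config$seed,
    n_genes = nrow(rcn), n_samples = ncol(rcn),
    amplicons = summary_amp,
    survival = if (!is.null(surv_cmp)) surv_cmp else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  echo <- unclass(config)
  echo$inputs <- lapply(config$inputs, as.character)
  yaml::write_yaml(echo, file.path(out_dir, "config_used.yaml"))
  writeLines(state$log, file.path(out_dir, "run.log"))

  invisible(list(results = results, cooccurrence = cooc,
                 survival = surv_cmp, summary = summary, log = state$log))
}
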