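#' Configuration for the synthetic amplification/dependency generator
#'
#' Builds fixture datasets with the statistical structure the pipeline
#' assumes: lineage-structured cell lines of known ploidy; one (or more)
#' planted contiguous amplicons whose member genes carry correlated high
#' copy numbers in a stated fraction of lines; collateral dependencies as
#' negative gene-effect shifts restricted to amplified lines; dosage-driven
#' versus dosage-buffered expression; and exponential survival with a stated
#' hazard ratio for amplified tumors. A ground-truth manifest accompanies
#' every bundle so that downstream modules can be tested for parameter
#' recovery.
#'
#' Defaults describe the reference fixture used throughout the test suite:
#' 2,000 genes by 200 cell lines, a 20-gene amplicon amplified in 30% of
#' lines at 8-16 absolute copies, five planted dependencies at
#' `delta_effect = -0.5` against gene-effect noise of 0.2, three of the five
#' dosage-expressed.
#'
#' @param n_genes,n_lines,n_lineages Genome, panel and lineage sizes.
#' @param ploidies Integer ploidy values lines are drawn from (uniformly).
#' @param amplicon_span Length-2 integer vector: first and last gene index of
#'   the planted contiguous amplicon core.
#' @param reference_index Gene index used as the amplicon's reference gene;
#'   default the middle of the span.
#' @param amplified_fraction Probability that a line carries the amplicon.
#' @param amp_copies_range Absolute-copy amplitude range for amplified lines;
#'   the lower bound must be >= 6 so planted amplifications are callable.
#' @param flank_width Genes on each side of the core span that are amplified
#'   with probability halving per gene of distance, producing partially
#'   correlated neighbors that fail the r >= 0.7 coamplification bar.
#' @param cn_noise_sd Per-gene copy noise (copies), truncated so copies stay
#'   non-negative.
#' @param dependent_genes Gene indices (within the span) carrying the planted
#'   collateral dependency.
#' @param delta_effect Planted gene-effect shift in amplified lines (must be
#'   negative: a dependency is deleterious).
#' @param effect_noise_sd Gene-effect noise standard deviation.
#' @param essential_genes,essential_effect Optional common-essential genes
#'   centered at `essential_effect` in every line.
#' @param dosage_genes Gene indices whose expression follows copy number
#'   (slope `dosage_slope`); other genes are dosage-buffered (slope 0).
#' @param dosage_slope Expression units (log2 TPM + 1 scale) per unit of
#'   stored relative copy number.
#' @param expr_baseline_mean,expr_baseline_sd Per-gene baseline expression.
#' @param lineage_sd Per gene-by-lineage expression offset scale.
#' @param expr_noise_sd Residual expression noise.
#' @param n_tumors Tumor cohort size for the survival table.
#' @param baseline_hazard Disease-death hazard in non-amplified tumors
#'   (default log 2: median survival of one time unit).
#' @param survival_hr Hazard ratio for amplified tumors (must be > 0).
#' @param other_hazard Amplification-independent other-cause death hazard;
#'   such deaths count as events for overall survival but censor
#'   disease-specific survival.
#' @param censor_time Administrative censoring time (may be `Inf`).
#' @param band_size Genes per synthetic chromosome band, used to build the
#'   positional gene-set collection.
#' @param extra_amplicons Optional list of additional planted amplicons, each
#'   a list with fields `span` (length-2), and optionally `amplified_fraction`
#'   and `share_with_primary` (fraction of the primary amplicon's amplified
#'   lines reused, for co-occurrence tests).
#' @param seed Integer seed; identical seed + config give bit-identical output.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_lines = 200, n_lineages = 4,
                       ploidies = c(2L, 3L),
                       amplicon_span = c(1001L, 1020L),
                       reference_index = NULL,
                       amplified_fraction = 0.3,
                       amp_copies_range = c(8, 16),
                       flank_width = 3L,
                       cn_noise_sd = 0.3,
                       dependent_genes = c(1004L, 1008L, 1011L, 1014L, 1017L),
                       delta_effect = -0.5,
                       effect_noise_sd = 0.2,
                       essential_genes = integer(),
                       essential_effect = -1,
                       dosage_genes = c(1004L, 1008L, 1011L),
                       dosage_slope = 1,
                       expr_baseline_mean = 6, expr_baseline_sd = 1,
                       lineage_sd = 0.5,
                       expr_noise_sd = 0.5,
                       n_tumors = 400,
                       baseline_hazard = log(2),
                       survival_hr = 2,
                       other_hazard = 0.05,
                       censor_time = 5,
                       band_size = 100L,
                       extra_amplicons = list(),
                       seed = 20230307L) {
  cfg <- as.list(environment())
  if (cfg$n_genes < 1 || cfg$n_lines < 2) stop("need n_genes >= 1 and n_lines >= 2", call. = FALSE)
  if (cfg$amplified_fraction < 0 || cfg$amplified_fraction > 1) {
    stop("amplified_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$amplicon_span) != 2L || cfg$amplicon_span[1L] > cfg$amplicon_span[2L] ||
      cfg$amplicon_span[1L] < 1L || cfg$amplicon_span[2L] > cfg$n_genes) {
    stop("amplicon_span must be an increasing index interval inside the genome", call. = FALSE)
  }
  if (cfg$amp_copies_range[1L] < 6) {
    stop("amp_copies_range lower bound must be >= 6; a weaker planted ",
         "amplification would not be callable at the ACN >= 6 bar", call. = FALSE)
  }
  span_idx <- seq(cfg$amplicon_span[1L], cfg$amplicon_span[2L])
  if (!all(cfg$dependent_genes %in% span_idx)) {
    stop("dependent_genes must fall inside amplicon_span", call. = FALSE)
  }
  if (!all(cfg$dosage_genes %in% seq_len(cfg$n_genes))) {
    stop("dosage_genes out of range", call. = FALSE)
  }
  if (is.null(cfg$reference_index)) {
    cfg$reference_index <- span_idx[ceiling(length(span_idx) / 2)]
  }
  if (!cfg$reference_index %in% span_idx) {
    stop("reference_index must fall inside amplicon_span", call. = FALSE)
  }
  if (cfg$survival_hr <= 0) stop("survival_hr must be positive", call. = FALSE)
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive", call. = FALSE)
  if (cfg$effect_noise_sd < 0 || cfg$cn_noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  for (amp in cfg$extra_amplicons) {
    if (is.null(amp$span) || length(amp$span) != 2L ||
        amp$span[1L] > amp$span[2L] || amp$span[2L] > cfg$n_genes) {
      stop("each extra amplicon needs a valid `span`", call. = FALSE)
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

sim_gene_ids <- function(config) sprintf("G%04d", seq_len(config$n_genes))
sim_line_ids <- function(config) sprintf("CL%04d", seq_len(config$n_lines))

#' Simulate relative copy numbers with a planted amplicon
#'
#' Background copies sit at the line's ploidy plus truncated Gaussian noise,
#' so no unamplified line approaches the amplification bar. Each amplified
#' line draws a shared amplitude `A ~ Uniform(amp_copies_range)` applied (plus
#' per-gene noise) across the core span; genes in the flank are amplified with
#' probability halving per gene of distance from the core, so their profiles
#' correlate only partially with the reference gene. Stored values are
#' `log2(copies / ploidy + 1)`.
#'
#' @param config A [sim_config()].
#' @return List with `rcn` (a copy-number [gene_matrix()]), `samples` (sample
#'   table), and `truth` (ground-truth manifest; see [simulate_bundle()]).
#' @export
simulate_copy_number <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sim_gene_ids(config)
  lines <- sim_line_ids(config)
  lineages <- sprintf("lineage%02d", seq_len(config$n_lineages))
  lineage <- sample(rep_len(lineages, config$n_lines))
  ploidy <- sample(config$ploidies, config$n_lines, replace = TRUE)

  copies <- matrix(rep(ploidy, each = config$n_genes), config$n_genes, config$n_lines) +
    stats::rnorm(config$n_genes * config$n_lines, 0, config$cn_noise_sd)
  copies <- pmax(copies, 0)
  dimnames(copies) <- list(genes, lines)

  primary <- list(span = config$amplicon_span,
                  amplified_fraction = config$amplified_fraction)
  amps <- c(list(primary), config$extra_amplicons)
  amp_truth <- vector("list", length(amps))
  primary_amp_idx <- integer()

  for (a in seq_along(amps)) {
    amp <- amps[[a]]
    frac <- if (is.null(amp$amplified_fraction)) config$amplified_fraction else amp$amplified_fraction
    if (!is.null(amp$share_with_primary) && a > 1L) {
      # reuse a stated fraction of the primary amplicon's amplified lines,
      # topped up with fresh lines to the same set size
      n_target <- length(primary_amp_idx)
      n_shared <- round(amp$share_with_primary * n_target)
      shared <- sample(primary_amp_idx, n_shared)
      pool <- setdiff(seq_len(config$n_lines), primary_amp_idx)
      fresh <- sample(pool, min(n_target - n_shared, length(pool)))
      amp_idx <- sort(c(shared, fresh))
    } else {
      amp_idx <- which(stats::runif(config$n_lines) < frac)
    }
    if (a == 1L) primary_amp_idx <- amp_idx
    span_idx <- seq(amp$span[1L], amp$span[2L])
    for (i in amp_idx) {
      A <- stats::runif(1L, config$amp_copies_range[1L], config$amp_copies_range[2L])
      copies[span_idx, i] <- pmax(A + stats::rnorm(length(span_idx), 0, config$cn_noise_sd), 0)
      if (config$flank_width > 0L) {
        # flank genes sit on separate breakpoint segments: inclusion starts
        # at 1/4 for the nearest neighbor and halves per gene of distance,
        # and the segment draws its own amplitude, so flank profiles only
        # partially track the reference gene (r well below the 0.7 bar)
        for (d in seq_len(config$flank_width)) {
          for (g in c(amp$span[1L] - d, amp$span[2L] + d)) {
            if (g >= 1L && g <= config$n_genes && stats::runif(1L) < 0.5^(d + 1L)) {
              A_seg <- stats::runif(1L, config$amp_copies_range[1L], config$amp_copies_range[2L])
              copies[g, i] <- pmax(A_seg + stats::rnorm(1L, 0, config$cn_noise_sd), 0)
            }
          }
        }
      }
    }
    ref_idx <- if (a == 1L) config$reference_index else {
      span_idx[ceiling(length(span_idx) / 2)]
    }
    amp_truth[[a]] <- list(reference_gene = genes[ref_idx],
                           span_genes = genes[span_idx],
                           amplified_lines = lines[amp_idx])
  }

  rcn_vals <- log2(sweep(copies, 2L, ploidy, "/") + 1)
  samples <- data.frame(sample_id = lines, lineage = lineage,
                        ploidy = ploidy, source = "cell_line",
                        stringsAsFactors = FALSE)
  span_idx <- seq(config$amplicon_span[1L], config$amplicon_span[2L])
  truth <- list(
    reference_gene = genes[config$reference_index],
    band = band_of_gene(config$reference_index, config),
    amplified_lines = amp_truth[[1L]]$amplified_lines,
    coamplified_genes = genes[span_idx],
    dependent_genes = genes[config$dependent_genes],
    dosage_genes = genes[config$dosage_genes],
    amplicons = amp_truth)
  attr(truth, "lineage_by_line") <- stats::setNames(lineage, lines)
  list(rcn = gene_matrix(rcn_vals, "copy_number"), samples = samples, truth = truth)
}

band_of_gene <- function(idx, config) {
  sprintf("band_%03d", (idx - 1L) %/% config$band_size + 1L)
}

#' Simulate CRISPR gene-effect scores
#'
#' Non-essential genes are centered at 0 (the score convention for a gene
#' whose knockout does not affect survival); optional common-essential genes
#' are centered at `essential_effect` in every line; planted dependent genes
#' are shifted by `delta_effect` only in amplified lines. Gaussian noise of
#' `effect_noise_sd` applies everywhere.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_copy_number()].
#' @return A gene-effect [gene_matrix()].
#' @export
simulate_gene_effects <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$delta_effect >= 0) {
    stop("delta_effect must be negative: a planted dependency is deleterious",
         call. = FALSE)
  }
  set.seed(config$seed + 1L)
  genes <- sim_gene_ids(config)
  lines <- sim_line_ids(config)
  eff <- matrix(stats::rnorm(config$n_genes * config$n_lines, 0, config$effect_noise_sd),
                config$n_genes, config$n_lines, dimnames = list(genes, lines))
  if (length(config$essential_genes)) {
    eff[config$essential_genes, ] <- eff[config$essential_genes, ] + config$essential_effect
  }
  amp_cols <- lines %in% truth$amplified_lines
  dep_rows <- match(truth$dependent_genes, genes)
  eff[dep_rows, amp_cols] <- eff[dep_rows, amp_cols] + config$delta_effect
  gene_matrix(eff, "gene_effect")
}

#' Simulate expression with dosage-driven and dosage-buffered genes
#'
#' Expression is a per-gene baseline plus a gene-by-lineage offset plus, for
#' dosage genes only, `dosage_slope` times the stored relative copy number,
#' plus residual noise. Values follow the log2(TPM + 1) scale convention.
#' Buffered genes (slope 0) reproduce the dissociation in which an amplified,
#' screen-significant gene shows no copy-number-to-expression coupling.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth from [simulate_copy_number()].
#' @param rcn The simulated copy-number matrix.
#' @return An expression [gene_matrix()].
#' @export
simulate_expression <- function(config, truth, rcn) {
  stopifnot(inherits(config, "sim_config"))
  assert_role(rcn, "copy_number")
  set.seed(config$seed + 2L)
  genes <- sim_gene_ids(config)
  lines <- sim_line_ids(config)
  lineages <- sprintf("lineage%02d", seq_len(config$n_lineages))
  # lineage of each line is re-derivable only from the sample table; re-draws
  # here would break determinism, so the offsets are indexed by lineage label
  baseline <- stats::rnorm(config$n_genes, config$expr_baseline_mean, config$expr_baseline_sd)
  offsets <- matrix(stats::rnorm(config$n_genes * config$n_lineages, 0, config$lineage_sd),
                    config$n_genes, config$n_lineages, dimnames = list(genes, lineages))
  line_lineage <- attr(truth, "lineage_by_line")
  expr <- matrix(baseline, config$n_genes, config$n_lines) +
    stats::rnorm(config$n_genes * config$n_lines, 0, config$expr_noise_sd)
  dimnames(expr) <- list(genes, lines)
  if (!is.null(line_lineage)) {
    expr <- expr + offsets[, line_lineage[lines], drop = FALSE]
  }
  slope_rows <- match(truth$dosage_genes, genes)
  expr[slope_rows, ] <- expr[slope_rows, ] + config$dosage_slope * unclass(rcn)[slope_rows, ]
  gene_matrix(expr, "expression")
}

#' Simulate a tumor survival table
#'
#' Tumors carry the amplification with probability `amplified_fraction`.
#' Disease-death times are exponential with hazard
#' `baseline_hazard * survival_hr^amplified`; other-cause deaths (hazard
#' `other_hazard`, amplification-independent) count as events for the OS
#' endpoint but censor the DSS endpoint; administrative censoring applies at
#' `censor_time`. Emitted in long format with one row per tumor and endpoint.
#'
#' @param config A [sim_config()].
#' @param truth Ground truth list; the amplified tumor set is appended to it
#'   by [simulate_bundle()].
#' @return A data.frame with columns `sample_id`, `time`, `event`, `endpoint`,
#'   `group`, `lineage`.
#' @export
simulate_survival <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$survival_hr <= 0) stop("survival_hr must be positive", call. = FALSE)
  set.seed(config$seed + 3L)
  n <- config$n_tumors
  ids <- sprintf("TU%04d", seq_len(n))
  lineages <- sprintf("lineage%02d", seq_len(config$n_lineages))
  lineage <- sample(rep_len(lineages, n))
  amplified <- stats::runif(n) < config$amplified_fraction
  hz <- config$baseline_hazard * ifelse(amplified, config$survival_hr, 1)
  t_disease <- stats::rexp(n, hz)
  t_other <- if (config$other_hazard > 0) stats::rexp(n, config$other_hazard) else rep(Inf, n)
  t_os <- pmin(t_disease, t_other)
  os_time <- pmin(t_os, config$censor_time)
  os_event <- as.integer(t_os <= config$censor_time)
  dss_event <- as.integer(t_disease <= t_other & t_disease <= config$censor_time)
  group <- ifelse(amplified, "amplified", "none_of_the_amplifications")
  long <- rbind(
    data.frame(sample_id = ids, time = os_time, event = os_event,
               endpoint = "OS", group = group, lineage = lineage,
               stringsAsFactors = FALSE),
    data.frame(sample_id = ids, time = os_time, event = dss_event,
               endpoint = "DSS", group = group, lineage = lineage,
               stringsAsFactors = FALSE))
  attr(long, "amplified_tumors") <- ids[amplified]
  long
}

#' Generate a complete synthetic fixture bundle
#'
#' Runs all four simulators under the config's seed and assembles the
#' matrices, sample table, survival table, positional gene sets, target
#' annotations and ground-truth manifest into one in-memory bundle.
#'
#' @param config A [sim_config()].
#' @return A list with elements `rcn`, `effects`, `expression`, `samples`,
#'   `survival`, `positional_sets`, `annotations`, `truth`, `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  cn <- simulate_copy_number(config)
  truth <- cn$truth
  effects <- simulate_gene_effects(config, truth)
  expression <- simulate_expression(config, truth, cn$rcn)
  surv <- simulate_survival(config, truth)
  truth$amplified_tumors <- attr(surv, "amplified_tumors")
  attr(truth, "lineage_by_line") <- NULL

  set.seed(config$seed + 4L)
  genes <- sim_gene_ids(config)
  locs <- c("membrane", "secreted", "cytoplasm", "nucleus", "organelle")
  annotations <- data.frame(
    gene_id = genes,
    localization = sample(locs, config$n_genes, replace = TRUE,
                          prob = c(0.2, 0.1, 0.3, 0.3, 0.1)),
    ligandability = round(stats::runif(config$n_genes, -3, 3), 2),
    stringsAsFactors = FALSE)

  list(rcn = cn$rcn, effects = effects, expression = expression,
       samples = cn$samples, survival = surv,
       positional_sets = build_positional_sets(config),
       annotations = annotations, truth = truth, config = config)
}

#' Positional gene sets for the synthetic genome
#'
#' Partitions the synthetic genome into consecutive bands of `band_size`
#' genes, mirroring a chromosome-band (C1-style) positional collection. The
#' planted amplicon falls inside one band, which parameter-recovery tests
#' expect the overlap analysis to rank first.
#'
#' @param config A [sim_config()].
#' @return Named list of gene-id vectors.
#' @export
build_positional_sets <- function(config) {
  genes <- sim_gene_ids(config)
  band <- (seq_len(config$n_genes) - 1L) %/% config$band_size + 1L
  sets <- split(genes, sprintf("band_%03d", band))
  for (nm in names(sets)) attr(sets[[nm]], "description") <- "synthetic chromosome band"
  sets[order(names(sets))]
}

#' Write / read a fixture bundle on disk
#'
#' Serializes every component through the package's standard writers:
#' `copy_number.csv`, `gene_effect.csv`, `expression.csv` (genes in rows,
#' first column the gene symbol), `samples.tsv`, `survival.tsv`,
#' `positional_sets.gmt`, `annotations.tsv` and `truth.json`. A read-back
#' through [read_fixture_bundle()] reproduces the in-memory objects.
#'
#' @param bundle A bundle from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gene_matrix(bundle$rcn, file.path(dir, "copy_number.csv"))
  write_gene_matrix(bundle$effects, file.path(dir, "gene_effect.csv"))
  write_gene_matrix(bundle$expression, file.path(dir, "expression.csv"))
  write_results_table(bundle$samples, file.path(dir, "samples.tsv"))
  write_results_table(bundle$survival, file.path(dir, "survival.tsv"))
  write_gmt(bundle$positional_sets, file.path(dir, "positional_sets.gmt"))
  write_results_table(bundle$annotations, file.path(dir, "annotations.tsv"))
  truth <- bundle$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(dir) {
  surv <- data.table::fread(file.path(dir, "survival.tsv"), sep = "\t",
                            header = TRUE, data.table = FALSE)
  list(
    rcn = read_gene_matrix(file.path(dir, "copy_number.csv"), "copy_number"),
    effects = read_gene_matrix(file.path(dir, "gene_effect.csv"), "gene_effect"),
    expression = read_gene_matrix(file.path(dir, "expression.csv"), "expression"),
    samples = read_sample_table(file.path(dir, "samples.tsv")),
    survival = surv,
    positional_sets = read_gmt(file.path(dir, "positional_sets.gmt")),
    annotations = read_target_annotations(file.path(dir, "annotations.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE))
}
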