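#' Kaplan-Meier curve and median survival
#'
#' Product-limit estimator via `survival::survfit`. Censored times reduce the
#' risk set without a step; the median is the first time at which the
#' survival curve drops to 0.5 or below, and is `NA` when the curve never
#' reaches 0.5 (e.g. everything censored).
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator, 1 = death, 0 = censored.
#' @return A list with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `surv`), `median`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("need at least one record", call. = FALSE)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  med <- curve$time[curve$surv <= 0.5]
  list(curve = curve,
       median = if (length(med)) med[1L] else NA_real_,
       n = length(time), n_events = sum(event))
}

#' Log-rank test with an O/E hazard-ratio estimate
#'
#' Standard one-degree-of-freedom log-rank statistic (observed minus expected
#' events with hypergeometric variance at each distinct event time; tied
#' events are handled by the simultaneous-event convention), via
#' `survival::survdiff`. The hazard ratio is estimated from the log-rank
#' table as `HR = (O_a / E_a) / (O_b / E_b)` — self-contained, though it can
#' differ slightly from a semi-parametric (Cox) fit.
#'
#' @param time_a,event_a,time_b,event_b Times and 0/1 event indicators for
#'   the two groups (a = amplified by convention).
#' @return A list with `chi2`, `p_value`, `hr_oe`, `observed`, `expected`
#'   (each length 2, group a first).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty", call. = FALSE)
  if (sum(event_a) + sum(event_b) == 0) stop("no events in either group", call. = FALSE)
  grp <- factor(rep(c("a", "b"), c(length(time_a), length(time_b))), levels = c("a", "b"))
  sd <- survival::survdiff(
    survival::Surv(c(time_a, time_b), c(event_a, event_b)) ~ grp)
  obs <- as.numeric(sd$obs)
  exp_ <- as.numeric(sd$exp)
  hr <- (obs[1L] / exp_[1L]) / (obs[2L] / exp_[2L])
  list(chi2 = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       hr_oe = hr, observed = obs, expected = exp_)
}

#' Compare survival between amplified and amplification-free samples
#'
#' For each amplification in the registry and each endpoint, compares samples
#' amplified at that reference gene against the control group of samples
#' amplified at none of the registry's genes: Kaplan-Meier medians, log-rank
#' chi-square and p, and the O/E hazard ratio. A sample amplified at two
#' registry genes contributes to both amplified groups and never to the
#' control. Optional per-lineage stratification repeats each comparison
#' within every tumor type separately.
#'
#' @param records Long-format survival table with columns `sample_id`,
#'   `time`, `event`, `endpoint`, and (for stratified reports) `lineage`.
#' @param amplified_sets Named list: for each reference gene, the amplified
#'   sample ids (an `amplification_calls` object is also accepted).
#' @param stratify_by_lineage Add per-lineage comparisons.
#' @return A data.frame with one row per amplification x endpoint (x lineage
#'   when stratified): `reference_gene`, `endpoint`, `lineage`,
#'   `n_amplified`, `n_control`, `median_amplified`, `median_control`,
#'   `logrank_chi2`, `p_value`, `hazard_ratio`.
#' @export
compare_survival <- function(records, amplified_sets, stratify_by_lineage = FALSE) {
  amplified_sets <- lapply(amplified_sets, function(x) {
    if (inherits(x, "amplification_calls")) x$amplified_samples else x
  })
  if (is.null(names(amplified_sets)) || any(!nzchar(names(amplified_sets)))) {
    stop("amplified_sets must be named by reference gene", call. = FALSE)
  }
  all_amp <- unique(unlist(amplified_sets, use.names = FALSE))
  control_ids <- setdiff(unique(records$sample_id), all_amp)
  if (!length(control_ids)) {
    stop("control group is empty: every sample carries some registry amplification",
         call. = FALSE)
  }
  scopes <- list(list(label = "all", rows = rep(TRUE, nrow(records))))
  if (stratify_by_lineage) {
    for (lin in unique(records$lineage)) {
      scopes <- c(scopes, list(list(label = lin, rows = records$lineage == lin)))
    }
  }
  out <- list()
  for (scope in scopes) {
    sub <- records[scope$rows, , drop = FALSE]
    for (ep in unique(sub$endpoint)) {
      ss <- sub[sub$endpoint == ep, , drop = FALSE]
      ctrl <- ss[ss$sample_id %in% control_ids, , drop = FALSE]
      for (gene in names(amplified_sets)) {
        amp <- ss[ss$sample_id %in% amplified_sets[[gene]], , drop = FALSE]
        if (nrow(amp) < 2L || nrow(ctrl) < 2L ||
            sum(amp$event) + sum(ctrl$event) == 0L) next
        lr <- logrank_test(amp$time, amp$event, ctrl$time, ctrl$event)
        out[[length(out) + 1L]] <- data.frame(
          reference_gene = gene, endpoint = ep, lineage = scope$label,
          n_amplified = nrow(amp), n_control = nrow(ctrl),
          median_amplified = km_estimate(amp$time, amp$event)$median,
          median_control = km_estimate(ctrl$time, ctrl$event)$median,
          logrank_chi2 = lr$chi2, p_value = lr$p_value,
          hazard_ratio = lr$hr_oe, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
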