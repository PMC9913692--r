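#' Derive risk-group thresholds from grade-aggregated marker means
#'
#' The stratification marker (exocrine-like proportion, MKI67 level, or any
#' per-sample score) is aggregated by grade group and adjacent group means
#' are averaged: threshold = (mean of lower group + mean of upper group) / 2.
#' The binary design uses the groups \{G1, G2\} versus \{G3\}; the ternary
#' design \{G1\}, \{G2\}, \{G3\} with two thresholds.
#'
#' @param marker_values Numeric per-sample marker values.
#' @param grading Per-sample grading (G1/G2/G3), parallel to
#'   `marker_values`; samples with missing grade are ignored.
#' @param arms `"binary"` or `"ternary"`.
#' @return Numeric vector of 1 (binary) or 2 (ternary, strictly increasing)
#'   thresholds.
#' @export
compute_thresholds <- function(marker_values, grading, arms = c("binary", "ternary")) {
  arms <- match.arg(arms)
  keep <- !is.na(marker_values) & !is.na(grading)
  marker_values <- marker_values[keep]
  grading <- grading[keep]
  groups <- if (arms == "binary") {
    list(low = c("G1", "G2"), high = "G3")
  } else {
    list(G1 = "G1", G2 = "G2", G3 = "G3")
  }
  means <- vapply(groups, function(g) {
    v <- marker_values[grading %in% g]
    if (!length(v)) stop("no samples in grade group {", paste(g, collapse = ","), "}")
    mean(v)
  }, numeric(1))
  if (any(diff(means) <= 0)) {
    stop("grade-group marker means are not strictly increasing: ",
         paste(sprintf("%s=%.4g", names(means), means), collapse = ", "))
  }
  (means[-length(means)] + means[-1L]) / 2
}

#' Assign risk groups by thresholding a marker
#'
#' Half-open binning with the threshold belonging to the upper group:
#' value < t1 is `low`; t1 <= value < t2 is `medium`; value >= last
#' threshold is `high`.
#'
#' @param marker_values Numeric per-sample marker values.
#' @param thresholds Ordered thresholds (1 for binary, 2 for ternary).
#' @return Character vector of group labels (`low`/`high`, or
#'   `low`/`medium`/`high`).
#' @export
stratify <- function(marker_values, thresholds) {
  thresholds <- sort(thresholds)
  labels <- if (length(thresholds) == 1L) c("low", "high") else
    c("low", "medium", "high")
  if (length(thresholds) > 2L) stop("at most 2 thresholds supported")
  labels[findInterval(marker_values, thresholds) + 1L]
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator with at-risk bookkeeping at the event times,
#' computed with the survival package. Each group's curve starts at
#' probability 1 at time 0 and is non-increasing.
#'
#' @param times Non-negative survival times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels; empty groups are skipped with a warning.
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_estimate <- function(times, events, groups) {
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  groups <- as.character(groups)
  empty <- setdiff(unique(groups), groups[!is.na(times)])
  if (length(empty)) warning("empty group(s) skipped: ", paste(empty, collapse = ", "))
  out <- lapply(sort(unique(groups)), function(g) {
    sel <- groups == g
    sf <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    # anchor the curve at S(0) = 1 unless an observation sits at time 0
    anchor <- !0 %in% sf$time
    data.frame(group = g,
               time = c(if (anchor) 0, sf$time),
               n_risk = c(if (anchor) sum(sel), sf$n.risk),
               n_event = c(if (anchor) 0, sf$n.event),
               survival = c(if (anchor) 1, sf$surv),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log-rank test and hazard ratio between risk groups
#'
#' Log-rank chi-square test across all groups (df = number of groups - 1);
#' for exactly two groups additionally a proportional-hazards ratio of the
#' second group level versus the first, with a 95% confidence interval
#' (partial likelihood, Efron tie handling) and its Wald p-value.
#'
#' @param times Non-negative survival times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List with `logrank_statistic`, `df`, `p_value` and, for two
#'   groups, `hazard_ratio`, `hr_ci` (length 2), `hr_p_value`.
#' @export
compare_groups <- function(times, events, groups) {
  groups <- factor(as.character(groups))
  if (nlevels(groups) < 2L) stop("need >= 2 non-empty groups")
  if (sum(events) == 0) stop("no events observed in any group")
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  stat <- sd_fit$chisq
  res <- list(logrank_statistic = unname(stat), df = df,
              p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
  if (nlevels(groups) == 2L) {
    cx <- survival::coxph(survival::Surv(times, events) ~ groups)
    s <- summary(cx)
    res$hazard_ratio <- unname(s$conf.int[1L, "exp(coef)"])
    res$hr_ci <- unname(s$conf.int[1L, c("lower .95", "upper .95")])
    res$hr_p_value <- unname(s$coefficients[1L, "Pr(>|z|)"])
  }
  res
}
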