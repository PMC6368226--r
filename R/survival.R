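#' Build survival records for an endpoint
#'
#' Overall survival (OS): time from surgery to death or last contact, event
#' = death. Metastasis-free survival (MFS): patients with a metastasis
#' already present at surgery are excluded; time is the earlier of the
#' metastasis and OS times and metastasis and death both count as events.
#' An optional horizon applies administrative censoring: follow-up beyond
#' the horizon is truncated there with event = 0.
#'
#' @param ann Cohort annotation with `sample_id`, `os_time`, `os_event`
#'   and, for MFS, `met_time`, `met_event`, `baseline_metastasis`. Times in
#'   months.
#' @param endpoint `"OS"` or `"MFS"`.
#' @param horizon_months Optional administrative-censoring horizon (e.g. 36
#'   or 60 months).
#' @return Data frame of class `survival_records` with `sample_id`, `time`,
#'   `event`, `endpoint`.
#' @export
build_endpoint <- function(ann, endpoint = c("OS", "MFS"),
                           horizon_months = NULL) {
  endpoint <- match.arg(endpoint)
  need <- c("sample_id", "os_time", "os_event")
  if (endpoint == "MFS")
    need <- c(need, "met_time", "met_event", "baseline_metastasis")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stopf("annotation missing clinical field(s): %s", paste(miss, collapse = ", "))
  num_cols <- intersect(c("os_time", "met_time"), need)
  for (cc in num_cols) {
    bad <- ann$sample_id[is.na(ann[[cc]]) | ann[[cc]] < 0]
    if (length(bad))
      stopf("negative or missing %s for record(s): %s", cc,
            paste(bad, collapse = ", "))
  }
  if (endpoint == "OS") {
    rec <- data.frame(sample_id = ann$sample_id, time = ann$os_time,
                      event = as.integer(ann$os_event),
                      stringsAsFactors = FALSE)
  } else {
    keep <- !(as.logical(ann$baseline_metastasis) %in% TRUE)
    a <- ann[keep, , drop = FALSE]
    tt <- pmin(a$met_time, a$os_time)
    ev <- as.integer((a$met_event == 1 & a$met_time <= a$os_time) |
                       (a$os_event == 1 & a$os_time <= a$met_time))
    rec <- data.frame(sample_id = a$sample_id, time = tt, event = ev,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(horizon_months)) {
    over <- rec$time > horizon_months
    rec$event[over] <- 0L
    rec$time[over] <- horizon_months
  }
  rec$endpoint <- endpoint
  structure(rec, class = c("survival_records", "data.frame"),
            horizon = horizon_months)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps `survival::survfit` with the standard convention that events
#' precede censorings at tied times.
#'
#' @param records A `survival_records` data frame (`time`, `event`).
#' @return A list of class `km_curve`: `time` (ascending unique observed
#'   times), `n_risk`, `n_event`, `n_censor`, `surv`, `n`.
#' @export
km_estimate <- function(records) {
  if (!nrow(records)) stopf("need at least one record")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(records))
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 surv = fit$surv, n = sum(fit$n)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d events, final S = %.3f at t = %g\n",
              x$n, sum(x$n_event), x$surv[length(x$surv)],
              max(x$time)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ..., xlab = "Time (months)",
                          ylab = "Survival fraction") {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 verticals = FALSE, xlim = c(0, max(x$time)),
                 ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step evaluation: S(t) is the survival fraction after
#' the last event time at or before `t`; 1 before the first observed time.
#' Times beyond the last observed time are an error (the curve is undefined
#' there).
#'
#' @param curve A `km_curve`.
#' @param t Time in months.
#' @return Survival fraction in `[0, 1]`.
#' @export
km_surv_at <- function(curve, t) {
  if (t > max(curve$time))
    stopf("t = %g is beyond the curve's follow-up (max %g)", t, max(curve$time))
  idx <- which(curve$time <= t)
  if (!length(idx)) return(1)
  curve$surv[max(idx)]
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom log-rank via `survival::survdiff`. When
#' neither group has any event the statistic is 0 with p = 1.
#'
#' @param group_a,group_b `survival_records` for the two groups.
#' @return List of class `logrank_test`: `chisq`, `p_value`, `n`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(group_a, group_b) {
  if (!nrow(group_a) || !nrow(group_b)) stopf("both groups must be non-empty")
  df <- rbind(
    data.frame(time = group_a$time, event = group_a$event, group = "A",
               stringsAsFactors = FALSE),
    data.frame(time = group_b$time, event = group_b$event, group = "B",
               stringsAsFactors = FALSE))
  if (sum(df$event) == 0) {
    return(structure(list(chisq = 0, p_value = 1, n = c(A = nrow(group_a),
                                                        B = nrow(group_b)),
                          observed = c(0, 0), expected = c(0, 0)),
                     class = "logrank_test"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  structure(list(chisq = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n = sd$n, observed = sd$obs, expected = sd$exp),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
              x$chisq, x$p_value))
  invisible(x)
}

#' Survival-fraction difference at a fixed horizon
#'
#' S_high(t) - S_low(t) in percentage points, so worse survival in the
#' high-score group comes out negative.
#'
#' @param curve_high,curve_low `km_curve` objects for the two groups.
#' @param t_months Horizon within both curves' follow-up.
#' @return Difference in percentage points.
#' @export
delta_surv <- function(curve_high, curve_low, t_months) {
  100 * (km_surv_at(curve_high, t_months) - km_surv_at(curve_low, t_months))
}
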