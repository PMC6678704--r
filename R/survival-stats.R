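# Survival statistics: Kaplan-Meier estimation, log-rank testing and Cox
# proportional-hazards fits with Wald inference, plus endpoint construction
# and administrative follow-up truncation. Estimation is delegated to the
# survival package; these wrappers fix the conventions used throughout the
# burden analysis (Breslow tie handling, 95% Wald intervals on the log-HR
# scale, events-before-censorings at tied times).

#' Administratively censor follow-up at a horizon
#'
#' Observations with follow-up beyond `horizon` are censored at the horizon
#' (time set to `horizon`, event flag cleared). An event occurring exactly at
#' the horizon is kept as an event: only strictly later times are touched.
#' Overall-survival models in this package are conventionally truncated at
#' five years.
#'
#' @param data data frame with numeric `time` (years, positive) and binary
#'   `event` columns; other columns pass through untouched.
#' @param horizon positive truncation time in years (default 5).
#' @return `data` with `time`/`event` truncated.
#' @export
truncate_followup <- function(data, horizon = 5) {
  check_surv(data$time, data$event)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stopf("`horizon` must be a single positive number")
  beyond <- data$time > horizon
  data$time[beyond] <- horizon
  data$event[beyond] <- 0
  data
}

#' @keywords internal
#' @noRd
check_surv <- function(time, event) {
  if (length(time) == 0L) stopf("empty survival data")
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0))
    stopf("survival times must be finite and strictly positive")
  if (!is_binary01(as.numeric(event)))
    stopf("event flags must be 0/1")
  if (length(time) != length(event))
    stopf("time and event lengths differ")
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit survival curve. At tied times events are
#' processed before censorings (the standard convention). With no censoring
#' the curve reduces to one minus the empirical distribution function of the
#' event times.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return object of class `km_curve`: a data frame with columns `time`
#'   (unique observed times, ascending), `n_risk`, `n_event`, `n_censor`
#'   and `surv`; S(0) = 1 is implicit (the curve starts at 1 before the
#'   first row).
#' @export
kaplan_meier <- function(time, event) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  out <- data.frame(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    surv = fit$surv
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", nrow(x), "time points,",
      sum(x$n_event), "events\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Time (years)",
                          ylab = "Survival probability", ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, main = "", ...)
  invisible(x)
}

#' Log-rank test for survival differences between groups
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance, compared to a chi-square distribution on (k - 1) degrees of
#' freedom for k groups.
#'
#' @param time,event survival outcome.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `chisq`, `df`, `p`, and the per-group observed and
#'   expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event)
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stopf("log-rank test needs >= 2 non-empty groups")
  if (sum(event) < 1L) stopf("log-rank test needs >= 1 event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(
    chisq = unname(sd$chisq),
    df = df,
    p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
    observed = sd$obs,
    expected = sd$exp
  )
}

#' Cox proportional-hazards fit with Wald inference
#'
#' Fits a Cox model by partial-likelihood maximization with Breslow handling
#' of tied event times (Efron available via `ties`). Reports, per covariate,
#' the coefficient, hazard ratio, 95% Wald confidence interval
#' exp(coef +/- 1.96 se) and two-sided Wald p-value. Aliased (collinear)
#' covariates are an error, as is apparent non-convergence.
#'
#' @param data data frame containing `time`, `event` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return object of class `cox_fit_result`: list with `table` (term, coef,
#'   se, hr, lower, upper, p), `loglik` (null, fitted), `score_chisq`
#'   (score test at beta = 0), `n`, `n_event`.
#' @export
cox_fit <- function(data, covariates, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  check_surv(data$time, data$event)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stopf("covariates absent from data: %s", paste(missing_cov, collapse = ", "))
  if (sum(data$event) < length(covariates) + 1L)
    stopf("too few events (%d) for %d covariates", sum(data$event),
          length(covariates))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite|did not converge|Loglik converged",
                conditionMessage(w))) {
        stopf("Cox fit failed: %s", conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stopf("collinear covariates detected (aliased terms: %s)",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  z <- cf / se
  out <- list(
    table = data.frame(
      term = names(cf),
      coef = unname(cf),
      se = unname(se),
      hr = exp(unname(cf)),
      lower = exp(unname(cf - 1.96 * se)),
      upper = exp(unname(cf + 1.96 * se)),
      p = 2 * stats::pnorm(-abs(unname(z)))
    ),
    loglik = fit$loglik,
    score_chisq = unname(fit$score),
    n = fit$n,
    n_event = fit$nevent
  )
  class(out) <- "cox_fit_result"
  out
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (Breslow ties): n = %d, events = %d\n",
              x$n, x$n_event))
  tab <- x$table
  tab$hr <- signif(tab$hr, 4)
  tab$lower <- signif(tab$lower, 4)
  tab$upper <- signif(tab$upper, 4)
  tab$p <- signif(tab$p, 3)
  print.data.frame(tab[, c("term", "hr", "lower", "upper", "p")],
                   row.names = FALSE)
  invisible(x)
}

#' Construct overall- and disease-free-survival endpoints
#'
#' From per-patient follow-up records, builds the two endpoints: overall
#' survival (time to death or last follow-up; event = death) and
#' disease-free survival (time to the first of relapse or death, else last
#' follow-up; event = relapse or death).
#'
#' @param records data frame with columns `sample_id`, `followup_years`
#'   (time to death or last follow-up), `death` (0/1), and optionally
#'   `relapse_years` (NA when no relapse observed).
#' @return list with `os` and `dfs` data frames (`sample_id`, `time`,
#'   `event`).
#' @export
make_endpoints <- function(records) {
  need <- c("sample_id", "followup_years", "death")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records missing columns: %s", paste(miss, collapse = ", "))
  if (any(records$followup_years <= 0, na.rm = TRUE) ||
      any(!is.finite(records$followup_years)))
    stopf("follow-up durations must be positive and finite")
  relapse <- if ("relapse_years" %in% names(records)) {
    records$relapse_years
  } else {
    rep(NA_real_, nrow(records))
  }
  if (any(relapse <= 0, na.rm = TRUE)) stopf("relapse durations must be positive")
  os <- data.frame(
    sample_id = records$sample_id,
    time = records$followup_years,
    event = as.integer(records$death)
  )
  dfs_time <- ifelse(!is.na(relapse),
                     pmin(relapse, records$followup_years),
                     records$followup_years)
  dfs_event <- as.integer(!is.na(relapse) | records$death == 1)
  dfs <- data.frame(sample_id = records$sample_id,
                    time = dfs_time, event = dfs_event)
  list(os = os, dfs = dfs)
}
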