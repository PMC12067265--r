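ct_check_survival <- function(records, require_groups = TRUE) {
  required <- c("patient_id", "time_days", "event", "group")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    abort(paste0("Survival records lack column(s): ",
                 paste(missing, collapse = ", ")), class = "ct_input_error")
  }
  if (any(records$time_days <= 0)) {
    abort("Survival times must be strictly positive.", class = "ct_input_error")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort("`event` must be 0 (censored) or 1 (event).", class = "ct_input_error")
  }
  if (require_groups) {
    lev <- unique(records$group)
    if (length(lev) != 2L) {
      abort("Exactly two group levels are required.", class = "ct_input_error")
    }
    if (any(table(records$group) == 0)) {
      abort("Each group needs at least one record.", class = "ct_input_error")
    }
  }
  records
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator at each distinct event time; censoring reduces
#' the at-risk count without a survival step.
#'
#' @param records tibble with `patient_id`, `time_days`, `event` (1 = event,
#'   0 = censored), `group`.
#' @return a `ct_km` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (plus a leading time-0 row per group).
#' @export
#' @examples
#' rec <- tibble::tibble(patient_id = paste0("p", 1:4),
#'                       time_days = c(1, 2, 1.5, 3),
#'                       event = c(1, 1, 0, 0), group = "all")
#' km_estimate(rec)
km_estimate <- function(records) {
  ct_check_survival(records, require_groups = FALSE)
  fit <- survival::survfit(
    survival::Surv(time_days, event) ~ group,
    data = as.data.frame(records))
  strata <- if (is.null(fit$strata)) {
    rep(unique(records$group)[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  steps <- tibble::tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor, survival = fit$surv)
  origin <- steps |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(time = 0, n_risk = max(.data$n_risk), n_event = 0L,
                     n_censor = 0L, survival = 1, .groups = "drop")
  out <- dplyr::bind_rows(origin, steps) |>
    dplyr::arrange(.data$group, .data$time)
  class(out) <- c("ct_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with the hypergeometric variance at each
#' distinct event time, one degree of freedom.
#'
#' @inheritParams km_estimate
#' @return a `ct_logrank` list: `chi_square`, `p_value`, `n_events`,
#'   `groups`, and `degenerate` (TRUE when no events occurred, in which
#'   case the statistic is 0 and p is 1).
#' @export
logrank_test <- function(records) {
  ct_check_survival(records)
  if (sum(records$event) == 0) {
    out <- list(chi_square = 0, p_value = 1, n_events = 0L,
                groups = sort(unique(records$group)), degenerate = TRUE)
    return(structure(out, class = "ct_logrank"))
  }
  sd <- survival::survdiff(
    survival::Surv(time_days, event) ~ group,
    data = as.data.frame(records), rho = 0)
  chi <- unname(sd$chisq)
  structure(list(
    chi_square = chi,
    p_value = pchisq(chi, df = 1, lower.tail = FALSE),
    n_events = as.integer(sum(records$event)),
    groups = sort(unique(records$group)),
    degenerate = FALSE
  ), class = "ct_logrank")
}

#' @method print ct_logrank
#' @export
print.ct_logrank <- function(x, ...) {
  cat("Log-rank test:", paste(x$groups, collapse = " vs "), "\n")
  cat(sprintf("  chi-square = %.4f (df = 1), p = %.4g, events = %d\n",
              x$chi_square, x$p_value, x$n_events))
  invisible(x)
}

#' Two-group Cox proportional-hazards estimate
#'
#' Maximum partial-likelihood estimate of the hazard ratio for a single
#' binary group covariate, Breslow tie handling, Wald 95% CI on the log
#' scale. The effect is reported for `reference_level` relative to the
#' other level (hazard of the non-reference group divided by the hazard of
#' the reference group).
#'
#' @inheritParams km_estimate
#' @param reference_level group level used as baseline; defaults to the
#'   first level in sort order.
#' @return a `ct_cox` list: `hazard_ratio`, `ci_low`, `ci_high`, `log_hr`,
#'   `se_log_hr`, `p_value`, `log_partial_likelihood`, `groups`,
#'   `reference`, `monotone` (TRUE when the likelihood diverges because one
#'   group has no events; the Wald interval is then one-sided and
#'   `hazard_ratio` is the boundary estimate returned by the fitter).
#' @export
cox_two_group <- function(records, reference_level = NULL) {
  ct_check_survival(records)
  lev <- sort(unique(records$group))
  if (!is.null(reference_level)) {
    if (!reference_level %in% lev) {
      abort("`reference_level` is not a group level.", class = "ct_input_error")
    }
    lev <- c(reference_level, setdiff(lev, reference_level))
  }
  df <- as.data.frame(records)
  df$group <- factor(df$group, levels = lev)
  events_by_group <- tapply(df$event, df$group, sum)
  monotone <- any(events_by_group == 0)
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(time_days, event) ~ group, data = df, ties = "breslow"))
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  structure(list(
    hazard_ratio = exp(beta),
    ci_low = exp(beta - qnorm(0.975) * se),
    ci_high = exp(beta + qnorm(0.975) * se),
    log_hr = beta,
    se_log_hr = se,
    p_value = 2 * pnorm(-abs(beta / se)),
    log_partial_likelihood = fit$loglik[2],
    groups = lev,
    reference = lev[1],
    monotone = monotone
  ), class = "ct_cox")
}

#' @method print ct_cox
#' @export
print.ct_cox <- function(x, ...) {
  cat("Cox proportional hazards (Breslow ties):",
      x$groups[2], "vs", x$reference, "\n")
  cat(sprintf("  HR = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$p_value))
  if (x$monotone) {
    cat("  note: no events in one group; estimate is a one-sided bound\n")
  }
  invisible(x)
}

#' Compare survival between diversity trajectory groups
#'
#' Joins per-patient trajectory labels onto survival records and runs the
#' Kaplan-Meier estimate, log-rank test, and two-group Cox fit, the
#' stratification used for induced-diversity survival analysis.
#'
#' @param trajectories tibble from [diversity_trajectories()] (needs
#'   `patient_id`, `increased`).
#' @param survival_records tibble with `patient_id`, `time_days`, `event`.
#' @return list with `km` ([km_estimate()]), `logrank` ([logrank_test()]),
#'   `cox` ([cox_two_group()]; hazard of the increased group relative to
#'   flat), and the joined `records`.
#' @export
survival_by_trajectory <- function(trajectories, survival_records) {
  joined <- survival_records |>
    dplyr::inner_join(dplyr::select(trajectories, "patient_id", "increased"),
                      by = "patient_id") |>
    dplyr::mutate(group = ifelse(.data$increased, "increased", "flat"))
  if (nrow(joined) == 0) {
    abort("No overlapping patients between trajectories and survival.",
          class = "ct_input_error")
  }
  list(
    km = km_estimate(joined),
    logrank = logrank_test(joined),
    cox = cox_two_group(joined, reference_level = "flat"),
    records = joined
  )
}
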