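#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-group Cox fit
#' @param x a `ct_cox` from [cox_two_group()].
#' @param ... unused.
#' @return one-row tibble with `term`, `estimate` (log HR), `std_error`,
#'   `hazard_ratio`, `conf_low`, `conf_high`, `p_value`.
#' @export
tidy.ct_cox <- function(x, ...) {
  tibble::tibble(
    term = paste0("group", x$groups[2]),
    estimate = x$log_hr,
    std_error = x$se_log_hr,
    hazard_ratio = x$hazard_ratio,
    conf_low = x$ci_low,
    conf_high = x$ci_high,
    p_value = x$p_value
  )
}

#' @rdname tidy.ct_cox
#' @export
glance.ct_cox <- function(x, ...) {
  tibble::tibble(
    log_partial_likelihood = x$log_partial_likelihood,
    monotone = x$monotone,
    reference = x$reference
  )
}

#' Tidy a log-rank test result
#' @param x a `ct_logrank` from [logrank_test()].
#' @param ... unused.
#' @return one-row tibble with `chi_square`, `df`, `p_value`, `n_events`.
#' @export
tidy.ct_logrank <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = 1L, p_value = x$p_value,
                 n_events = x$n_events, degenerate = x$degenerate)
}

#' Tidy a fitted trajectory predictor
#' @param x a `ct_predictor` from [train_predictor()].
#' @param ... unused.
#' @return the withheld-set prediction tibble.
#' @export
tidy.ct_predictor <- function(x, ...) {
  if (is.null(x$withheld)) {
    abort("Imported models carry no withheld set.", class = "ct_input_error")
  }
  x$withheld
}

#' @rdname tidy.ct_predictor
#' @export
glance.ct_predictor <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    n_hidden = x$n_hidden,
    withheld_accuracy = x$withheld_accuracy,
    n_withheld = if (is.null(x$withheld)) NA_integer_ else nrow(x$withheld),
    seed = x$seed
  )
}

#' Tidy a triad occurrence result
#' @param x a `ct_triad`.
#' @param ... unused.
#' @return one-row tibble of the observed statistic and (when present) its
#'   permutation null summary.
#' @export
tidy.ct_triad <- function(x, ...) {
  tibble::tibble(
    type_a = x$types[1], type_b = x$types[2], type_c = x$types[3],
    radius_um = x$radius_um, mode = x$mode,
    n_proximal_pairs = x$n_proximal_pairs, n_with_c = x$n_with_c,
    occurrence_probability = x$occurrence_probability,
    null_mean = x$null_mean %||% NA_real_,
    null_sd = x$null_sd %||% NA_real_,
    z = x$z %||% NA_real_,
    p_value = x$p_value %||% NA_real_,
    undefined = x$undefined
  )
}

#' Tidy a neighborhood enrichment result
#' @param x a `ct_enrichment`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
tidy.ct_enrichment <- function(x, ...) {
  tibble::tibble(
    type_a = x$type_a, type_b = x$type_b, n_observed = x$n_observed,
    null_mean = x$null_mean, null_sd = x$null_sd, z = x$z,
    p_value = x$p_value, undefined = x$undefined
  )
}
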