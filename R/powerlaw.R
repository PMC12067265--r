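#' Sample clone sizes from a truncated discrete power law
#'
#' Immune repertoires are heavy-tailed: a few clones are large, most are
#' singletons. Clone sizes are drawn from the discrete distribution
#' \eqn{P(k) \propto k^{-\alpha}} on \eqn{k = 1, \dots, k_{max}}.
#'
#' @param n number of clone sizes to draw.
#' @param alpha power-law exponent (> 1).
#' @param k_max truncation point (default 1000).
#' @return integer vector of length `n`.
#' @seealso [fit_powerlaw_exponent()]
#' @export
#' @examples
#' sizes <- withr::with_seed(1, rpowerlaw(500, alpha = 2.5))
#' mean(sizes == 1) # most clones are singletons
rpowerlaw <- function(n, alpha, k_max = 1000L) {
  alpha <- assert_positive(alpha, "alpha")
  if (alpha <= 1) abort("`alpha` must exceed 1.", class = "ct_config_error")
  k_max <- assert_count(k_max, "k_max", min = 2)
  k <- seq_len(k_max)
  pmf <- k^(-alpha)
  sample.int(k_max, size = n, replace = TRUE, prob = pmf)
}

#' Maximum-likelihood exponent of a truncated discrete power law
#'
#' Fits \eqn{\alpha} by maximizing the truncated zeta log-likelihood
#' over a bracket, by golden-section search.
#'
#' @param sizes integer vector of clone sizes (>= 1).
#' @param k_max truncation point used when sampling.
#' @param interval search bracket for alpha.
#' @return the ML estimate of alpha (numeric scalar).
#' @export
fit_powerlaw_exponent <- function(sizes, k_max = 1000L, interval = c(1.01, 6)) {
  if (length(sizes) == 0 || any(sizes < 1)) {
    abort("`sizes` must be a nonempty vector of counts >= 1.",
          class = "ct_input_error")
  }
  k <- seq_len(k_max)
  sum_log <- sum(log(sizes))
  n <- length(sizes)
  # negative log-likelihood: n * log(normalizer) + alpha * sum(log k_i)
  optimize(function(a) n * log(sum(k^(-a))) + a * sum_log, interval)$minimum
}
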