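#' Generate a labeled expression matrix with planted differential genes
#'
#' Samples-by-genes normalized (linear-scale, log-normal) expression for a
#' pretreatment cohort labeled by eventual BCR trajectory. A chosen set of
#' genes is shifted `fold_change`-fold in the `increase` group; everything
#' else is exchangeable noise.
#'
#' @param n_per_group samples per label group.
#' @param n_genes total genes.
#' @param n_de number of planted differential genes (default 117).
#' @param fold_change planted fold shift (default 2.5).
#' @param noise_sd log-scale noise standard deviation (default 0.5).
#' @param seed integer seed.
#' @return list with `matrix` (rownames are sample ids), `labels`,
#'   `de_genes` (planted truth).
#' @export
generate_labeled_matrix <- function(n_per_group = 30L, n_genes = 2000L,
                                    n_de = 117L, fold_change = 2.5,
                                    noise_sd = 0.5, seed = 1L) {
  n_per_group <- assert_count(n_per_group, "n_per_group")
  n_genes <- assert_count(n_genes, "n_genes")
  n_de <- assert_count(n_de, "n_de", min = 0)
  if (n_de > n_genes) {
    abort("`n_de` exceeds `n_genes`.", class = "ct_config_error")
  }
  with_seed(seed, {
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    de_genes <- genes[seq_len(n_de)]
    n <- 2L * n_per_group
    labels <- rep(c("increase", "no_increase"), each = n_per_group)
    base <- exp(rnorm(n_genes, mean = 2, sd = 1))
    mu <- matrix(rep(base, each = n), nrow = n)
    mu[labels == "increase", seq_len(n_de)] <-
      mu[labels == "increase", seq_len(n_de)] * fold_change
    m <- mu * exp(matrix(rnorm(n * n_genes, 0, noise_sd), nrow = n))
    dimnames(m) <- list(sprintf("sample%03d", seq_len(n)), genes)
    list(matrix = m, labels = labels, de_genes = de_genes)
  })
}

#' Generate an external validation cohort with a treatment-specific benefit
#'
#' Builds an independent cohort for the two-step validation of the
#' trajectory predictor: per patient, a latent true trajectory label, a
#' pretreatment expression profile carrying the planted differential
#' signature of that label, a treatment arm (`pd1` or `control`), and a
#' survival record whose hazard depends on the latent label only in the
#' PD-1 arm. The control arm has no opportunity for a checkpoint-specific
#' benefit, so a specific predictor should stratify survival only in the
#' PD-1 arm.
#'
#' @param n_per_arm patients per arm.
#' @param n_genes,n_de,fold_change,noise_sd as in
#'   [generate_labeled_matrix()]; use the same values as the training
#'   cohort so the planted signature matches.
#' @param hazard_ratio hazard ratio of true-increase patients in the PD-1
#'   arm (default 0.46).
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censor_time_days right-censoring horizon.
#' @param seed integer seed.
#' @return list with `matrix`, `truth` (tibble: `patient_id`, `arm`,
#'   `true_label`), `survival` (tibble: `patient_id`, `time_days`,
#'   `event`, `arm`).
#' @export
generate_prediction_cohort <- function(n_per_arm = 60L, n_genes = 2000L,
                                       n_de = 117L, fold_change = 2.5,
                                       noise_sd = 0.5, hazard_ratio = 0.46,
                                       baseline_hazard = 1 / 500,
                                       censor_time_days = 2564,
                                       seed = 1L) {
  with_seed(seed, {
    n <- 2L * n_per_arm
    ids <- sprintf("ext%03d", seq_len(n))
    arm <- rep(c("pd1", "control"), each = n_per_arm)
    true_inc <- runif(n) < 0.5
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    base <- exp(rnorm(n_genes, mean = 2, sd = 1))
    mu <- matrix(rep(base, each = n), nrow = n)
    mu[true_inc, seq_len(n_de)] <- mu[true_inc, seq_len(n_de)] * fold_change
    m <- mu * exp(matrix(rnorm(n * n_genes, 0, noise_sd), nrow = n))
    dimnames(m) <- list(ids, genes)
    rate <- baseline_hazard *
      ifelse(arm == "pd1" & true_inc, hazard_ratio, 1)
    t <- rexp(n, rate)
    list(
      matrix = m,
      truth = tibble::tibble(patient_id = ids, arm = arm,
                             true_label = ifelse(true_inc, "increase",
                                                 "no_increase")),
      survival = tibble::tibble(
        patient_id = ids,
        time_days = pmin(t, censor_time_days),
        event = as.integer(t <= censor_time_days),
        arm = arm)
    )
  })
}
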