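#' Differential expression between diversity trajectory groups
#'
#' Per-gene Wilcoxon rank-sum test between the `increase` and
#' `no_increase` groups on normalized expression, Benjamini-Hochberg
#' q-values, and the log2 fold change of group means. Genes are selected at
#' `q < q_threshold` and `|log2FC| >= lfc_threshold`; the fold-change sign
#' convention is increase-group minus no-increase-group. All-zero genes
#' are excluded with a flag.
#'
#' @param matrix samples-by-genes matrix of normalized (linear-scale)
#'   expression, sample ids as rownames.
#' @param labels character/factor of `"increase"` / `"no_increase"` per
#'   sample (at least 3 per group).
#' @param q_threshold,lfc_threshold selection thresholds (defaults 0.05
#'   and 1).
#' @return a `ct_de` tibble: `gene`, `log2_fc`, `p`, `q`, `selected`,
#'   `excluded`.
#' @export
differential_expression <- function(matrix, labels, q_threshold = 0.05,
                                    lfc_threshold = 1) {
  labels <- as.character(labels)
  if (!all(labels %in% c("increase", "no_increase"))) {
    abort("Labels must be 'increase' or 'no_increase'.",
          class = "ct_input_error")
  }
  if (length(unique(labels)) < 2L || min(table(labels)) < 3L) {
    abort("Each label group needs at least 3 samples.",
          class = "ct_input_error")
  }
  inc <- labels == "increase"
  excluded <- colSums(matrix) == 0
  p <- rep(NA_real_, ncol(matrix))
  lfc <- rep(NA_real_, ncol(matrix))
  eps <- 1e-9
  for (g in which(!excluded)) {
    x <- matrix[inc, g]
    y <- matrix[!inc, g]
    p[g] <- suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    lfc[g] <- log2((mean(x) + eps) / (mean(y) + eps))
  }
  q <- rep(NA_real_, length(p))
  q[!excluded] <- p.adjust(p[!excluded], method = "BH")
  out <- tibble::tibble(
    gene = colnames(matrix), log2_fc = lfc, p = p, q = q,
    selected = !excluded & !is.na(q) & q < q_threshold &
      abs(lfc) >= lfc_threshold,
    excluded = excluded
  )
  class(out) <- c("ct_de", class(out))
  out
}

# forward pass of the single-hidden-layer network from its weight vector
# (nnet weight layout: per hidden unit bias+inputs, then output bias+hidden)
ct_nn_forward <- function(x, wts, n_hidden) {
  p <- ncol(x)
  w1 <- matrix(wts[seq_len(n_hidden * (p + 1L))], nrow = p + 1L)
  w2 <- wts[n_hidden * (p + 1L) + seq_len(n_hidden + 1L)]
  h <- 1 / (1 + exp(-(cbind(1, x) %*% w1)))
  as.vector(1 / (1 + exp(-(cbind(1, h) %*% w2))))
}

#' Train the BCR-trajectory classifier
#'
#' Fits a single-hidden-layer feed-forward network (logistic activations,
#' cross-entropy loss) on standardized expression of the selected
#' differential genes, with a seeded stratified train/withheld split.
#' Identical data and seed reproduce the identical model; prediction is a
#' pure function of the stored weight vector, so exported models reload
#' bit-stably.
#'
#' @param matrix samples-by-genes normalized expression matrix.
#' @param labels `"increase"` / `"no_increase"` per sample.
#' @param de_genes genes to use as inputs (order fixed in the model).
#' @param split_fraction withheld fraction (default 0.2).
#' @param n_hidden hidden-layer width (default 32).
#' @param decay,maxit weight decay and iteration cap passed to the fitter.
#' @param seed training seed (split and weight initialization).
#' @return a `ct_predictor` list: `genes`, `center`, `scale`, `wts`,
#'   `n_hidden`, `seed`, `withheld_accuracy`, `withheld` (sample ids,
#'   truth, score, prediction), `train_samples`.
#' @export
train_predictor <- function(matrix, labels, de_genes, split_fraction = 0.2,
                            n_hidden = 32L, decay = 0.01, maxit = 200L,
                            seed = 1L) {
  if (!length(de_genes)) {
    abort("`de_genes` must be nonempty.", class = "ct_input_error")
  }
  missing <- setdiff(de_genes, colnames(matrix))
  if (length(missing)) {
    abort(paste0("Input matrix lacks gene(s): ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "ct_input_error")
  }
  labels <- as.character(labels)
  x <- matrix[, de_genes, drop = FALSE]
  y <- as.integer(labels == "increase")

  split_once <- function(s) {
    with_seed(s, {
      withheld <- unlist(lapply(split(seq_along(y), y), function(idx) {
        k <- max(1L, round(split_fraction * length(idx)))
        sample(idx, k)
      }), use.names = FALSE)
      sort(withheld)
    })
  }
  withheld_idx <- split_once(mix_seed(seed, "split"))
  tries <- 1L
  while (length(unique(y[withheld_idx])) < 2L && tries < 20L) {
    warn("Withheld set missing a class; re-splitting.")
    tries <- tries + 1L
    withheld_idx <- split_once(mix_seed(seed, paste0("split", tries)))
  }
  if (length(unique(y[withheld_idx])) < 2L) {
    abort("Could not form a withheld set containing both classes.",
          class = "ct_input_error")
  }
  train_idx <- setdiff(seq_along(y), withheld_idx)

  center <- colMeans(x[train_idx, , drop = FALSE])
  scl <- apply(x[train_idx, , drop = FALSE], 2, sd)
  scl[scl == 0 | is.na(scl)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")

  fit <- with_seed(mix_seed(seed, "weights"), {
    nnet::nnet(x = xs[train_idx, , drop = FALSE], y = y[train_idx],
               size = n_hidden, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE,
               MaxNWts = (length(de_genes) + 2L) * n_hidden + n_hidden + 1L)
  })
  score_w <- ct_nn_forward(xs[withheld_idx, , drop = FALSE], fit$wts, n_hidden)
  pred_w <- ifelse(score_w >= 0.5, "increase", "no_increase")
  acc <- mean(pred_w == labels[withheld_idx])
  structure(list(
    genes = de_genes,
    center = center,
    scale = scl,
    wts = fit$wts,
    n_hidden = as.integer(n_hidden),
    seed = as.integer(seed),
    withheld_accuracy = acc,
    withheld = tibble::tibble(
      sample_id = rownames(matrix)[withheld_idx] %||%
        as.character(withheld_idx),
      truth = labels[withheld_idx], score = score_w, predicted = pred_w),
    train_samples = rownames(matrix)[train_idx] %||%
      as.character(train_idx)
  ), class = "ct_predictor")
}

#' @method print ct_predictor
#' @export
print.ct_predictor <- function(x, ...) {
  cat("<ct_predictor>", length(x$genes), "input genes,",
      x$n_hidden, "hidden units\n")
  cat(sprintf("  withheld accuracy: %.1f%% (n = %d)\n",
              100 * x$withheld_accuracy, nrow(x$withheld)))
  invisible(x)
}

#' Export / import a trained predictor as a JSON weight manifest
#'
#' @param model a `ct_predictor`.
#' @param path file path for the JSON manifest.
#' @return `export_predictor` returns `path` invisibly; `import_predictor`
#'   returns the reloaded `ct_predictor` (numerically identical
#'   predictions).
#' @export
export_predictor <- function(model, path) {
  stopifnot(inherits(model, "ct_predictor"))
  # doubles are stored as %.17g strings so the manifest round-trips
  # bit-exactly regardless of the JSON writer's numeric formatting
  manifest <- list(
    format = "ct_predictor", version = 1L,
    genes = model$genes, center = sprintf("%.17g", unname(model$center)),
    scale = sprintf("%.17g", unname(model$scale)),
    wts = sprintf("%.17g", model$wts),
    n_hidden = model$n_hidden, seed = model$seed,
    withheld_accuracy = model$withheld_accuracy
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname export_predictor
#' @export
import_predictor <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$format, "ct_predictor")) {
    abort("Not a predictor manifest.", class = "ct_parse_error")
  }
  structure(list(
    genes = m$genes,
    center = setNames(as.numeric(m$center), m$genes),
    scale = setNames(as.numeric(m$scale), m$genes),
    wts = as.numeric(m$wts), n_hidden = as.integer(m$n_hidden),
    seed = as.integer(m$seed),
    withheld_accuracy = m$withheld_accuracy,
    withheld = NULL, train_samples = NULL
  ), class = "ct_predictor")
}

#' Predict the diversity trajectory for an external cohort
#'
#' Deterministic class and score per sample. Model genes missing from the
#' external matrix are imputed at the training mean (reported, up to 20% of
#' the inputs; more is refused). By default the external cohort is
#' harmonized by per-cohort gene-wise standardization; set
#' `harmonize = FALSE` to standardize with the training statistics instead.
#' Extra genes in the external matrix are ignored.
#'
#' @param model a `ct_predictor`.
#' @param external_matrix samples-by-genes normalized expression matrix.
#' @param harmonize logical (default TRUE).
#' @return tibble with `sample_id`, `score`, `predicted`,
#'   `low_confidence` (score within 0.1 of the decision boundary);
#'   attribute `n_imputed` reports imputed gene count.
#' @export
predict_trajectory <- function(model, external_matrix, harmonize = TRUE) {
  stopifnot(inherits(model, "ct_predictor"))
  if (is.null(dim(external_matrix)) || nrow(external_matrix) == 0) {
    abort("External matrix is empty.", class = "ct_input_error")
  }
  missing <- setdiff(model$genes, colnames(external_matrix))
  if (length(missing) > 0.2 * length(model$genes)) {
    abort(paste0(length(missing), " of ", length(model$genes),
                 " model genes missing (> 20%): refusing to predict."),
          class = "ct_input_error")
  }
  x <- matrix(NA_real_, nrow = nrow(external_matrix),
              ncol = length(model$genes),
              dimnames = list(rownames(external_matrix), model$genes))
  present <- intersect(model$genes, colnames(external_matrix))
  x[, present] <- as.matrix(external_matrix[, present, drop = FALSE])
  if (length(missing)) {
    warn(paste0("Imputing ", length(missing),
                " missing model gene(s) at training means."))
  }
  if (harmonize) {
    center <- colMeans(x[, , drop = FALSE], na.rm = TRUE)
    scl <- apply(x, 2, sd, na.rm = TRUE)
    scl[scl == 0 | is.na(scl)] <- 1
    center[is.na(center)] <- 0
  } else {
    center <- model$center
    scl <- model$scale
  }
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  xs[is.na(xs)] <- 0 # imputed at the (standardized) training mean
  score <- ct_nn_forward(xs, model$wts, model$n_hidden)
  out <- tibble::tibble(
    sample_id = rownames(external_matrix) %||%
      as.character(seq_len(nrow(external_matrix))),
    score = score,
    predicted = ifelse(score >= 0.5, "increase", "no_increase"),
    low_confidence = abs(score - 0.5) < 0.1
  )
  attr(out, "n_imputed") <- length(missing)
  out
}

#' Survival stratification by predicted trajectory, per treatment arm
#'
#' Joins predictions onto survival records and, within each treatment arm,
#' compares predicted classes by log-rank test and two-group Cox fit. The
#' non-PD-1 control arm serves as the specificity check: a trajectory
#' signal specific to checkpoint blockade should stratify only the PD-1
#' arm.
#'
#' @param predictions tibble from [predict_trajectory()] with `sample_id`
#'   matching `patient_id` in `survival`.
#' @param survival tibble with `patient_id`, `time_days`, `event`, and the
#'   arm column.
#' @param arm_col name of the treatment-arm column (default `"arm"`).
#' @return tibble with one row per arm: `arm`, `n`, `n_predicted_increase`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `logrank_chi_square`,
#'   `logrank_p`, `defined` (FALSE when an arm has a single predicted
#'   class).
#' @export
evaluate_predictions <- function(predictions, survival, arm_col = "arm") {
  if (!arm_col %in% names(survival)) {
    abort(paste0("Survival table lacks arm column '", arm_col, "'."),
          class = "ct_input_error")
  }
  joined <- survival |>
    dplyr::inner_join(
      dplyr::select(predictions, patient_id = "sample_id", "predicted"),
      by = "patient_id")
  if (nrow(joined) == 0) {
    abort("Predictions and survival share no patients.",
          class = "ct_input_error")
  }
  joined |>
    dplyr::group_by(arm = .data[[arm_col]]) |>
    dplyr::group_modify(function(df, key) {
      classes <- unique(df$predicted)
      if (length(classes) < 2L) {
        return(tibble::tibble(
          n = nrow(df), n_predicted_increase = sum(df$predicted == "increase"),
          hazard_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          logrank_chi_square = NA_real_, logrank_p = NA_real_,
          defined = FALSE))
      }
      rec <- dplyr::transmute(df, patient_id = .data$patient_id,
                              time_days = .data$time_days,
                              event = .data$event, group = .data$predicted)
      lr <- logrank_test(rec)
      cx <- cox_two_group(rec, reference_level = "no_increase")
      tibble::tibble(
        n = nrow(df), n_predicted_increase = sum(df$predicted == "increase"),
        hazard_ratio = cx$hazard_ratio, ci_low = cx$ci_low,
        ci_high = cx$ci_high, logrank_chi_square = lr$chi_square,
        logrank_p = lr$p_value, defined = TRUE)
    }) |>
    dplyr::ungroup()
}
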