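#' Per-sample pseudobulk profiles
#'
#' Library-size-normalizes each cell to a common depth, applies `log1p`,
#' and averages over each sample's cells, optionally excluding ("blinding")
#' one cluster. Samples left with zero cells after blinding are dropped and
#' reported in the `dropped_samples` attribute.
#'
#' @param counts cell-by-gene count matrix with cell ids as rownames.
#' @param cell_metadata tibble with `cell_id`, `sample_id`, `cluster`
#'   covering every row of `counts`.
#' @param blind_cluster optional cluster label to exclude.
#' @param scale_to library size target for normalization.
#' @return a wide tibble: `sample_id`, `cells_used`, then one column per
#'   gene with the sample's mean normalized expression.
#' @export
pseudobulk <- function(counts, cell_metadata, blind_cluster = NULL,
                       scale_to = 1e4) {
  if (!all(c("cell_id", "sample_id", "cluster") %in% names(cell_metadata))) {
    abort("`cell_metadata` needs cell_id, sample_id, cluster.",
          class = "ct_input_error")
  }
  meta <- cell_metadata[match(rownames(counts), cell_metadata$cell_id), ]
  if (any(is.na(meta$sample_id))) {
    abort("Every cell in `counts` must appear in `cell_metadata`.",
          class = "ct_input_error")
  }
  known <- if (is.factor(cell_metadata$cluster)) {
    levels(cell_metadata$cluster)
  } else {
    unique(cell_metadata$cluster)
  }
  if (!is.null(blind_cluster)) {
    # a known label with zero cells is a no-op blinding, not an error
    if (!blind_cluster %in% known) {
      abort(paste0("Unknown cluster label '", blind_cluster, "'."),
            class = "ct_input_error")
    }
    keep <- meta$cluster != blind_cluster
  } else {
    keep <- rep(TRUE, nrow(counts))
  }
  all_samples <- unique(meta$sample_id)
  norm <- normalize_log1p(counts[keep, , drop = FALSE], scale_to = scale_to)
  grp <- meta$sample_id[keep]
  sums <- rowsum(as.matrix(norm), group = grp)
  n_used <- as.vector(table(grp)[rownames(sums)])
  prof <- sums / n_used
  dropped <- setdiff(all_samples, rownames(prof))
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(prof), cells_used = n_used),
    tibble::as_tibble(prof)
  )
  attr(out, "dropped_samples") <- dropped
  out
}

ct_profile_matrix <- function(profiles) {
  genes <- setdiff(names(profiles), c("sample_id", "cells_used"))
  m <- as.matrix(profiles[, genes, drop = FALSE])
  rownames(m) <- profiles$sample_id
  m
}

#' Correlate per-sample gene expression with BCR clonotype counts
#'
#' Pearson correlation of each gene's pseudobulk value against the sample's
#' unique BCR clonotype count, across samples, with Benjamini-Hochberg
#' q-values over all tested genes. Genes with zero variance across samples
#' are flagged and excluded from testing.
#'
#' @param profiles wide pseudobulk tibble from [pseudobulk()].
#' @param bcr_counts tibble with `sample_id` and `n_unique` (e.g. from
#'   [count_unique_clonotypes()]).
#' @return tibble with `gene`, `r`, `p`, `q`, `n_samples`, `zero_variance`.
#' @export
gene_diversity_correlation <- function(profiles, bcr_counts) {
  common <- intersect(profiles$sample_id, bcr_counts$sample_id)
  if (length(common) < 4L) {
    abort("Fewer than 4 overlapping samples between profiles and counts.",
          class = "ct_input_error")
  }
  m <- ct_profile_matrix(profiles)[common, , drop = FALSE]
  y <- bcr_counts$n_unique[match(common, bcr_counts$sample_id)]
  v <- apply(m, 2, var)
  zero_var <- v == 0 | var(y) == 0
  r <- rep(NA_real_, ncol(m))
  n <- length(common)
  r[!zero_var] <- suppressWarnings(as.vector(cor(m[, !zero_var, drop = FALSE], y)))
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- rep(NA_real_, length(p))
  q[!zero_var] <- p.adjust(p[!zero_var], method = "BH")
  tibble::tibble(gene = colnames(m), r = r, p = p, q = q,
                 n_samples = n, zero_variance = zero_var)
}

#' Cluster-blinded attribution of gene-diversity correlations
#'
#' For each gene and cluster, the change in correlation strength when the
#' cluster's cells are blinded from the pseudobulk:
#' `delta = |R_full| - |R_blinded|`. A positive delta means the cluster
#' carries the correlation. Clusters whose blinding would empty more than
#' half of the samples are skipped with a warning.
#'
#' @param counts cell-by-gene count matrix.
#' @param cell_metadata tibble with `cell_id`, `sample_id`, `cluster`.
#' @param bcr_counts tibble with `sample_id`, `n_unique`.
#' @param genes genes to attribute (default: all non-zero-variance genes).
#' @return a `ct_attribution` list: `base` (full-data
#'   [gene_diversity_correlation()] table), `delta` (long tibble `gene`,
#'   `cluster`, `r_blinded`, `delta`), `cluster_sizes`, and
#'   `skipped_clusters`.
#' @export
cluster_blinding_delta <- function(counts, cell_metadata, bcr_counts,
                                   genes = NULL) {
  clusters <- if (is.factor(cell_metadata$cluster)) {
    levels(cell_metadata$cluster)
  } else {
    sort(unique(cell_metadata$cluster))
  }
  if (length(clusters) < 2L) {
    abort("Attribution needs at least 2 clusters.", class = "ct_input_error")
  }
  full <- pseudobulk(counts, cell_metadata)
  base <- gene_diversity_correlation(full, bcr_counts)
  if (is.null(genes)) {
    genes <- base$gene[!base$zero_variance]
  }
  missing <- setdiff(genes, base$gene)
  if (length(missing)) {
    abort(paste0("Gene(s) not in the matrix: ",
                 paste(head(missing, 5), collapse = ", ")),
          class = "ct_input_error")
  }
  base_sel <- base[match(genes, base$gene), ]
  n_samples_full <- length(unique(cell_metadata$sample_id))

  deltas <- list()
  skipped <- character()
  for (cl in clusters) {
    prof <- pseudobulk(counts, cell_metadata, blind_cluster = cl)
    if (length(attr(prof, "dropped_samples")) > 0.5 * n_samples_full) {
      warn(paste0("Cluster '", cl, "' skipped: blinding empties >50% of samples."))
      skipped <- c(skipped, cl)
      next
    }
    blinded <- gene_diversity_correlation(prof, bcr_counts)
    bl <- blinded[match(genes, blinded$gene), ]
    deltas[[cl]] <- tibble::tibble(
      gene = genes, cluster = cl,
      r_blinded = bl$r,
      delta = abs(base_sel$r) - abs(bl$r)
    )
  }
  sizes <- cell_metadata |>
    dplyr::count(.data$cluster, name = "n_cells")
  structure(list(
    base = base,
    delta = dplyr::bind_rows(deltas),
    cluster_sizes = sizes,
    skipped_clusters = skipped
  ), class = "ct_attribution")
}

#' @method print ct_attribution
#' @export
print.ct_attribution <- function(x, ...) {
  cat("<ct_attribution>", length(unique(x$delta$gene)), "genes x",
      length(unique(x$delta$cluster)), "clusters\n")
  top <- x$delta |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$delta, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::count(.data$cluster, sort = TRUE)
  cat("  top attributed cluster:", top$cluster[1],
      sprintf("(%d genes)\n", top$n[1]))
  invisible(x)
}

#' Select genes for attribution display
#'
#' The `k` most correlated, `k` most anticorrelated, and `k` random other
#' eligible genes (seeded, drawn without replacement), as disjoint lists.
#' Ties in `r` are broken lexicographically by gene name.
#'
#' @param base_correlation tibble from [gene_diversity_correlation()].
#' @param k list size (default 25).
#' @param seed seed for the random list.
#' @return list with `top`, `random`, `bottom` character vectors.
#' @export
select_display_genes <- function(base_correlation, k = 25L, seed = 1L) {
  eligible <- base_correlation |>
    dplyr::filter(!.data$zero_variance, !is.na(.data$r)) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$gene)
  if (nrow(eligible) < 3L * k) {
    abort(paste0("Need at least ", 3L * k, " eligible genes."),
          class = "ct_input_error")
  }
  top <- eligible$gene[seq_len(k)]
  rest <- eligible |>
    dplyr::filter(!.data$gene %in% top) |>
    dplyr::arrange(.data$r, .data$gene)
  bottom <- rest$gene[seq_len(k)]
  remainder <- setdiff(rest$gene, bottom)
  random <- with_seed(seed, sample(remainder, k))
  list(top = top, random = random, bottom = bottom)
}
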