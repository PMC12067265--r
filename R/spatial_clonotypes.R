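ct_t_cell_types <- function() {
  c("CD8 T cell", "Activated CD8 T cell", "CD4 T cell", "Tfh",
    "Memory CD8 T cell", "Exhausted CD8 T cell")
}
ct_b_cell_types <- function() c("B cell", "Plasma cell")

ct_probe_columns <- function(cells, locus_class) {
  pat <- if (locus_class == "IGH") "^IGHV" else "^TR[AB]V"
  grep(pat, names(cells), value = TRUE)
}

#' Assign spatial cells to V-gene pseudoclones
#'
#' Each eligible cell (B-lineage for IGH, T-lineage for TCR) is assigned to
#' the pseudoclone of its maximal-count V-gene probe; ties break
#' lexicographically by gene name and all-zero cells stay unassigned.
#' Cells of the wrong lineage that nevertheless carry probe counts of the
#' requested class are skipped with a warning. BCR pseudoclones use IGH V
#' genes only: the heavy chain is the only chain whose usage fingerprint is
#' matched between modalities.
#'
#' @param cells spatial cell tibble (`cell_id`, `cell_type`, one column per
#'   V-gene probe; see [generate_spatial_sample()]).
#' @param locus_class `"TCR"` or `"IGH"`.
#' @return tibble with `cell_id`, `cell_type`, `locus_class`, `v_gene` for
#'   assigned cells.
#' @export
assign_pseudoclones <- function(cells, locus_class = c("TCR", "IGH")) {
  locus_class <- match.arg(locus_class)
  probe_cols <- ct_probe_columns(cells, locus_class)
  if (!length(probe_cols)) {
    abort(paste0("No ", locus_class, " V-gene probe columns found."),
          class = "ct_input_error")
  }
  eligible_types <- if (locus_class == "IGH") ct_b_cell_types()
                    else ct_t_cell_types()
  m <- as.matrix(cells[, probe_cols, drop = FALSE])
  has_counts <- rowSums(m) > 0
  eligible <- cells$cell_type %in% eligible_types
  n_skip <- sum(has_counts & !eligible)
  if (n_skip > 0) {
    warn(paste0(n_skip, " cell(s) with ", locus_class,
                " probe counts but an inconsistent cell type were skipped."))
  }
  use <- eligible & has_counts
  if (!any(use)) {
    return(tibble::tibble(cell_id = character(), cell_type = character(),
                          locus_class = character(), v_gene = character()))
  }
  # lexicographic tie-break: scan genes in name order, keep first argmax
  ord <- order(probe_cols)
  msub <- m[use, probe_cols[ord], drop = FALSE]
  best <- max.col(msub, ties.method = "first")
  tibble::tibble(
    cell_id = cells$cell_id[use],
    cell_type = cells$cell_type[use],
    locus_class = locus_class,
    v_gene = probe_cols[ord][best]
  )
}

#' Pseudoclone sizes
#' @param assignments tibble from [assign_pseudoclones()].
#' @return tibble with `locus_class`, `v_gene`, `size`.
#' @export
pseudoclone_sizes <- function(assignments) {
  assignments |>
    dplyr::count(.data$locus_class, .data$v_gene, name = "size")
}

#' V-gene usage frequencies from pseudoclone assignments
#'
#' Cell-level usage (one vote per assigned cell), comparable to
#' [vgene_usage()] on repertoire tables via [usage_correlation()].
#'
#' @param assignments tibble from [assign_pseudoclones()].
#' @param universe optional V-gene universe for the frequency vector.
#' @return tibble with `v_gene`, `frequency`.
#' @export
pseudoclone_usage <- function(assignments, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(assignments$v_gene))
  tallies <- assignments |>
    dplyr::count(.data$v_gene, name = "n")
  out <- tibble::tibble(v_gene = universe) |>
    dplyr::left_join(tallies, by = "v_gene") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  tot <- sum(out$n)
  out$frequency <- if (tot > 0) out$n / tot else 0
  dplyr::select(out, "v_gene", "frequency")
}

#' Proximity graph of spatial cells
#'
#' Undirected edges between all cell pairs with Euclidean distance less
#' than or equal to `radius_um` (inclusive boundary). Exact: computed by
#' blocked all-pairs distances.
#'
#' @param cells tibble with `cell_id`, `x_um`, `y_um`.
#' @param radius_um proximity radius in micrometers (default 20).
#' @return tibble with `cell_a`, `cell_b` (ids, a before b in input order),
#'   `distance_um`.
#' @export
proximity_graph <- function(cells, radius_um = 20) {
  radius_um <- assert_positive(radius_um, "radius_um")
  n <- nrow(cells)
  if (n < 2L) {
    return(tibble::tibble(cell_a = character(), cell_b = character(),
                          distance_um = numeric()))
  }
  x <- cells$x_um
  y <- cells$y_um
  block <- 512L
  res_i <- list()
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    dx <- outer(x[s:e], x, "-")
    dy <- outer(y[s:e], y, "-")
    d2 <- dx * dx + dy * dy
    hit <- which(d2 <= radius_um^2, arr.ind = TRUE)
    i <- hit[, 1] + s - 1L
    j <- hit[, 2]
    keep <- i < j
    res_i[[length(res_i) + 1L]] <- tibble::tibble(
      i = i[keep], j = j[keep],
      distance_um = sqrt(d2[hit[keep, , drop = FALSE]])
    )
  }
  edges <- dplyr::bind_rows(res_i)
  tibble::tibble(cell_a = cells$cell_id[edges$i],
                 cell_b = cells$cell_id[edges$j],
                 distance_um = edges$distance_um)
}

# integer edge list (i, j) for internal reuse
ct_edge_index <- function(cells, radius_um) {
  g <- proximity_graph(cells, radius_um)
  list(i = match(g$cell_a, cells$cell_id),
       j = match(g$cell_b, cells$cell_id),
       distance = g$distance_um)
}

#' Neighborhood enrichment of two cell types
#'
#' Permutation z-score for the number of proximal type-a/type-b cell pairs,
#' against a null that shuffles cell-type labels over fixed positions.
#'
#' @param cells spatial cell tibble (`cell_id`, `x_um`, `y_um`, `cell_type`).
#' @param type_a,type_b the two cell types.
#' @param radius_um proximity radius.
#' @param n_permutations number of label permutations (>= 100).
#' @param seed permutation seed.
#' @return a `ct_enrichment` list: `type_a`, `type_b`, `n_observed`,
#'   `null_mean`, `null_sd`, `z`, `p_value` (empirical, add-one smoothed),
#'   `undefined` (TRUE when a type is absent or no pair can form).
#' @export
neighborhood_enrichment <- function(cells, type_a, type_b, radius_um = 20,
                                    n_permutations = 1000L, seed = 1L) {
  n_permutations <- assert_count(n_permutations, "n_permutations", min = 100)
  lab <- cells$cell_type
  n_a <- sum(lab == type_a)
  n_b <- sum(lab == type_b)
  undefined <- n_a == 0 || n_b == 0 ||
    (type_a == type_b && n_a < 2L)
  if (undefined) {
    return(structure(list(type_a = type_a, type_b = type_b,
                          n_observed = NA_integer_, null_mean = NA_real_,
                          null_sd = NA_real_, z = NA_real_,
                          p_value = NA_real_, undefined = TRUE),
                     class = "ct_enrichment"))
  }
  edges <- ct_edge_index(cells, radius_um)
  count_pairs <- function(l) {
    if (type_a == type_b) {
      sum(l[edges$i] == type_a & l[edges$j] == type_a)
    } else {
      sum((l[edges$i] == type_a & l[edges$j] == type_b) |
          (l[edges$i] == type_b & l[edges$j] == type_a))
    }
  }
  observed <- count_pairs(lab)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(k) count_pairs(sample(lab)), numeric(1))
  })
  mu <- mean(null_counts)
  sdv <- sd(null_counts)
  z <- if (sdv > 0) (observed - mu) / sdv else NA_real_
  p <- (sum(null_counts >= observed) + 1) / (n_permutations + 1)
  structure(list(type_a = type_a, type_b = type_b,
                 n_observed = observed, null_mean = mu, null_sd = sdv,
                 z = z, p_value = p, undefined = FALSE),
            class = "ct_enrichment")
}

#' @method print ct_enrichment
#' @export
print.ct_enrichment <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("Neighborhood enrichment: undefined (type absent)\n")
  } else {
    cat(sprintf("Neighborhood enrichment %s ~ %s: observed %d, null %.1f +- %.1f, z = %.2f, p = %.4g\n",
                x$type_a, x$type_b, x$n_observed, x$null_mean, x$null_sd,
                x$z, x$p_value))
  }
  invisible(x)
}

#' T/B pseudoclone colocalization with a permutation null
#'
#' Assigns pseudoclones on both sides, counts proximal T/B member links for
#' every (T pseudoclone, B pseudoclone) pair, and scores each pair against
#' a null that permutes V-gene assignments within T cells and within B
#' cells at fixed positions and cell types. A pair is called colocalized
#' when its enrichment z-score reaches `z_threshold` (default 2).
#'
#' @param cells spatial cell tibble.
#' @param radius_um proximity radius (default 20).
#' @param n_permutations permutations of the V-gene labels (>= 100).
#' @param seed permutation seed.
#' @param z_threshold z-score at or above which a pair is flagged
#'   colocalized.
#' @param min_links minimum observed proximal links for the colocalized
#'   flag (default 2): singleton pseudoclones produce a near-degenerate
#'   permutation null in which one chance link already yields an extreme
#'   z-score.
#' @return tibble with `t_gene`, `b_gene`, `n_links`, `null_mean`,
#'   `null_sd`, `z`, `colocalized`, plus `t_size`, `b_size` pseudoclone
#'   sizes.
#' @export
pseudoclone_colocalization <- function(cells, radius_um = 20,
                                       n_permutations = 1000L, seed = 1L,
                                       z_threshold = 3, min_links = 2L) {
  n_permutations <- assert_count(n_permutations, "n_permutations", min = 100)
  t_assign <- assign_pseudoclones(cells, "TCR")
  b_assign <- assign_pseudoclones(cells, "IGH")
  if (nrow(t_assign) == 0 || nrow(b_assign) == 0) {
    return(tibble::tibble(t_gene = character(), b_gene = character(),
                          n_links = integer(), null_mean = numeric(),
                          null_sd = numeric(), z = numeric(),
                          colocalized = logical(), t_size = integer(),
                          b_size = integer()))
  }
  t_gene_of <- setNames(t_assign$v_gene, t_assign$cell_id)
  b_gene_of <- setNames(b_assign$v_gene, b_assign$cell_id)
  edges <- ct_edge_index(cells, radius_um)
  a_id <- cells$cell_id[edges$i]
  b_id <- cells$cell_id[edges$j]
  # orient every T-B edge as (T cell, B cell)
  t_first <- a_id %in% names(t_gene_of) & b_id %in% names(b_gene_of)
  b_first <- a_id %in% names(b_gene_of) & b_id %in% names(t_gene_of)
  t_cells_e <- c(a_id[t_first], b_id[b_first])
  b_cells_e <- c(b_id[t_first], a_id[b_first])

  t_genes <- sort(unique(t_assign$v_gene))
  b_genes <- sort(unique(b_assign$v_gene))
  nT <- length(t_genes)
  nB <- length(b_genes)
  # per-edge indices into the assignment vectors, for fast relabeling
  te <- match(t_cells_e, t_assign$cell_id)
  be <- match(b_cells_e, b_assign$cell_id)
  t_idx_assign <- match(t_assign$v_gene, t_genes)
  b_idx_assign <- match(b_assign$v_gene, b_genes)

  pair_counts <- function(t_lab, b_lab) {
    if (!length(te)) return(integer(nT * nB))
    pid <- (t_lab[te] - 1L) * nB + b_lab[be]
    tabulate(pid, nbins = nT * nB)
  }
  observed <- pair_counts(t_idx_assign, b_idx_assign)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      pair_counts(sample(t_idx_assign), sample(b_idx_assign))
    }, numeric(nT * nB))
  })
  if (nT * nB == 1L) nulls <- matrix(nulls, nrow = 1L)
  mu <- rowMeans(nulls)
  sdv <- apply(nulls, 1, sd)
  z <- ifelse(sdv > 0, (observed - mu) / sdv, NA_real_)
  sizes_t <- table(t_assign$v_gene)
  sizes_b <- table(b_assign$v_gene)
  out <- tidyr::expand_grid(t_gene = t_genes, b_gene = b_genes)
  # expand_grid varies b_gene fastest, matching the (t-1)*nB + b indexing
  out$n_links <- as.integer(observed)
  out$null_mean <- mu
  out$null_sd <- sdv
  out$z <- z
  out$colocalized <- !is.na(z) & z >= z_threshold & observed >= min_links
  out$t_size <- as.integer(sizes_t[out$t_gene])
  out$b_size <- as.integer(sizes_b[out$b_gene])
  out
}

#' Pseudoclone size correlation by treatment and colocalization stratum
#'
#' Spearman correlation of paired T and B pseudoclone sizes within each
#' (treatment, colocalization) stratum. Strata with fewer than `min_pairs`
#' pairs, or zero size variance on either side, are reported undefined.
#'
#' @param pair_table tibble with columns `treated`, `colocalized`,
#'   `t_size`, `b_size` — e.g. rows of [pseudoclone_colocalization()]
#'   results bound across samples with a `treated` column added.
#' @param min_pairs minimum pairs per stratum (default 4).
#' @return tibble with `treated`, `colocalized`, `n_pairs`, `rho`,
#'   `defined`.
#' @export
size_correlation_by_colocalization <- function(pair_table, min_pairs = 4L) {
  pair_table |>
    dplyr::group_by(.data$treated, .data$colocalized) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      rho = if (dplyr::n() >= min_pairs &&
                var(.data$t_size) > 0 && var(.data$b_size) > 0) {
        suppressWarnings(cor(.data$t_size, .data$b_size, method = "spearman"))
      } else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(defined = !is.na(.data$rho))
}

#' Tumor/lymph-node sharing of pseudoclone pairs
#'
#' Among (T, B) pseudoclone pairs present in the lymph-node sample (both
#' member pseudoclones detected with at least one cell), the fraction whose
#' member V genes are both also detected in the patient's tumor sample,
#' computed separately for colocalized and non-colocalized lymph-node
#' pairs.
#'
#' @param ln_coloc [pseudoclone_colocalization()] table for the lymph-node
#'   sample (its rows define the lymph-node pair universe).
#' @param tumor_cells spatial cell tibble for the tumor sample.
#' @return a `ct_sharing` one-row tibble: `n_colocalized`,
#'   `n_noncolocalized`, `fraction_shared_colocalized`,
#'   `fraction_shared_noncolocalized`, `ratio` (NA when a denominator is
#'   empty or the non-colocalized sharing fraction is 0).
#' @export
shared_pair_fraction <- function(ln_coloc, tumor_cells) {
  if (nrow(ln_coloc) == 0) {
    abort("No lymph-node pseudoclone pairs: sharing undefined.",
          class = "ct_undefined_error")
  }
  tumor_t <- unique(assign_pseudoclones(tumor_cells, "TCR")$v_gene)
  tumor_b <- unique(assign_pseudoclones(tumor_cells, "IGH")$v_gene)
  shared <- ln_coloc$t_gene %in% tumor_t & ln_coloc$b_gene %in% tumor_b
  coloc <- ln_coloc$colocalized
  f_col <- if (any(coloc)) mean(shared[coloc]) else NA_real_
  f_non <- if (any(!coloc)) mean(shared[!coloc]) else NA_real_
  ratio <- if (!is.na(f_col) && !is.na(f_non) && f_non > 0) f_col / f_non
           else NA_real_
  out <- tibble::tibble(
    n_colocalized = sum(coloc),
    n_noncolocalized = sum(!coloc),
    fraction_shared_colocalized = f_col,
    fraction_shared_noncolocalized = f_non,
    ratio = ratio
  )
  class(out) <- c("ct_sharing", class(out))
  out
}

#' Expression of compartment-shared vs exclusive T cell clones
#'
#' Compares marker expression between T cells of pseudoclones detected in
#' both compartments ("shared") and T cells of pseudoclones seen in only
#' one ("exclusive"), per compartment: mean log1p-count difference
#' (shared minus exclusive) with a Wilcoxon rank-sum p-value.
#'
#' @param cells spatial cell tibble covering both compartments (needs a
#'   `compartment` column and the expression columns named in `genes`).
#' @param genes genes to compare (default MKI67, CD69, ENTPD1).
#' @return tibble with `compartment`, `gene`, `n_shared`, `n_exclusive`,
#'   `effect`, `p_value`, `skipped` (TRUE when the gene is absent or a
#'   group is empty).
#' @export
shared_vs_exclusive_expression <- function(cells,
                                           genes = c("MKI67", "CD69",
                                                     "ENTPD1")) {
  if (!length(genes)) {
    abort("`genes` must be nonempty.", class = "ct_input_error")
  }
  assign <- assign_pseudoclones(cells, "TCR")
  by_comp <- cells |>
    dplyr::inner_join(dplyr::select(assign, "cell_id", "v_gene"),
                      by = "cell_id")
  comps <- unique(by_comp$compartment)
  gene_comp <- split(unique(by_comp[, c("v_gene", "compartment")])$v_gene,
                     unique(by_comp[, c("v_gene", "compartment")])$compartment)
  shared_genes <- if (length(comps) >= 2L) {
    Reduce(intersect, gene_comp)
  } else character()
  rows <- list()
  for (comp in comps) {
    sub <- by_comp[by_comp$compartment == comp, ]
    is_shared <- sub$v_gene %in% shared_genes
    for (g in genes) {
      if (!g %in% names(sub)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          compartment = comp, gene = g, n_shared = NA_integer_,
          n_exclusive = NA_integer_, effect = NA_real_, p_value = NA_real_,
          skipped = TRUE)
        next
      }
      xs <- log1p(sub[[g]][is_shared])
      xe <- log1p(sub[[g]][!is_shared])
      if (!length(xs) || !length(xe)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          compartment = comp, gene = g, n_shared = length(xs),
          n_exclusive = length(xe), effect = NA_real_, p_value = NA_real_,
          skipped = TRUE)
        next
      }
      wt <- suppressWarnings(wilcox.test(xs, xe))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        compartment = comp, gene = g,
        n_shared = length(xs), n_exclusive = length(xe),
        effect = mean(xs) - mean(xe), p_value = wt$p.value,
        skipped = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}
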