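#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic cohort: repertoire rates, clone-size
#' tail, V-gene usage, expression model, planted gene-diversity correlation,
#' spatial maps, and survival. Defaults emulate the study conditions of an
#' anti-PD-1-treated skin-cancer cohort with paired pre/post tumor biopsies:
#' a 93-patient survival cohort with a planted hazard ratio of 0.46 for
#' patients whose unique BCR clonotype count rises after treatment,
#' right-censoring at 2,564 days of follow-up, a 480-gene expression panel,
#' and a 20 micron spatial proximity radius.
#'
#' @param n_patients number of patients; each contributes a pre and a post
#'   treatment sample.
#' @param fraction_increased fraction of patients planted with induced BCR
#'   diversification (post rate = `post_clonotype_rate_increased`).
#' @param pre_clonotype_rate Poisson mean of unique BCR clonotypes in
#'   pre-treatment samples.
#' @param post_clonotype_rate_increased,post_clonotype_rate_flat Poisson
#'   means for post-treatment unique BCR clonotype counts in the two planted
#'   groups. The post draw is conditioned on the planted ordering (strictly
#'   greater than pre for "increased" patients, less than or equal for
#'   "flat") so the truth label is exactly recoverable from the tables.
#' @param tcr_clonotype_rate Poisson mean for unique TCR clonotypes at both
#'   timepoints (no planted treatment effect, mirroring the lack of a TCR
#'   survival association).
#' @param clone_size_alpha exponent of the truncated discrete power law for
#'   clone sizes (> 1).
#' @param clone_size_max truncation point of the clone-size distribution.
#' @param n_vgenes number of V genes per locus universe.
#' @param vgene_concentration symmetric Dirichlet concentration for
#'   sample-specific V-gene usage. Heavy-chain (IGH) and TR usage are drawn
#'   once per patient-timepoint and shared across modalities; light-chain
#'   (IGK/IGL) usage is drawn independently per sample, so only IGH carries
#'   a matched-sample signal.
#' @param n_genes size of the expression gene panel.
#' @param n_cells_per_sample cells per sample in the expression matrix.
#' @param nb_mean,nb_dispersion negative-binomial baseline mean and
#'   dispersion (size) for expression counts.
#' @param n_clusters number of cell clusters (max 9 named types).
#' @param marker_fold mean fold-up of a cluster's marker genes.
#' @param planted_corr_genes genes whose expression in
#'   `planted_corr_cluster` is shifted monotonically with the sample's
#'   unique BCR clonotype count.
#' @param planted_corr_cluster cluster carrying the planted correlation; use
#'   `"all"` to spread the same signal uniformly over every cluster (the
#'   attribution control condition), or `NULL` for no planted signal.
#' @param planted_corr_strength target Pearson correlation (in `[0,1]`)
#'   between per-sample pseudobulk of the planted genes and the BCR count.
#' @param spatial_field_um side of the square spatial field, micrometers.
#' @param n_cells_spatial background cells per spatial map.
#' @param proximity_radius_um proximity radius used when planting spatial
#'   structure (default 20).
#' @param n_planted_pairs number of planted (TR V, IGH V) pseudoclone pairs
#'   per patient; pair genes are matched diagonally. An equal number of
#'   non-colocalized "exclusive" genes per side completes the lymph-node
#'   V-gene pool.
#' @param colocalization_rate fraction of B cells of a planted pseudoclone
#'   that seed a paired T cell within the proximity radius (treated maps
#'   only).
#' @param triad_rate fraction of B cells in lymph-node maps anchoring a
#'   planted `triad_types` triad.
#' @param triad_types the three cell types of planted triads.
#' @param sharing_rate_colocalized probability that both genes of a planted
#'   colocalized lymph-node pair are also seeded into the patient's tumor.
#' @param sharing_rate_exclusive independent per-gene probability that any
#'   other lymph-node V gene is seeded into the tumor.
#' @param shared_expression_fold planted fold-elevation of marker expression
#'   (MKI67/CD69/ENTPD1) in T cells of compartment-shared clones.
#' @param hazard_ratio_increased hazard ratio of the planted "increased"
#'   group (default 0.46).
#' @param baseline_hazard baseline exponential hazard per day.
#' @param censor_time_days fixed right-censoring horizon (days).
#' @param seed integer seed driving the hierarchical seed tree.
#'
#' @return a validated `ct_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 6, seed = 7)
#' cfg$hazard_ratio_increased
cohort_config <- function(n_patients = 93,
                          fraction_increased = 0.5,
                          pre_clonotype_rate = 40,
                          post_clonotype_rate_increased = 80,
                          post_clonotype_rate_flat = 40,
                          tcr_clonotype_rate = 60,
                          clone_size_alpha = 2.5,
                          clone_size_max = 50L,
                          n_vgenes = 25L,
                          vgene_concentration = 0.5,
                          n_genes = 480L,
                          n_cells_per_sample = 400L,
                          nb_mean = 0.3,
                          nb_dispersion = 2,
                          n_clusters = 8L,
                          marker_fold = 5,
                          planted_corr_genes = c("CD69", "IFNG", "TNF"),
                          planted_corr_cluster = "Activated CD8 T cell",
                          planted_corr_strength = 0.4,
                          spatial_field_um = 1000,
                          n_cells_spatial = 1500L,
                          proximity_radius_um = 20,
                          n_planted_pairs = 10L,
                          colocalization_rate = 0.5,
                          triad_rate = 0.3,
                          triad_types = c("B cell", "Tfh", "Activated CD8 T cell"),
                          sharing_rate_colocalized = 0.3,
                          sharing_rate_exclusive = 0.08,
                          shared_expression_fold = 2,
                          hazard_ratio_increased = 0.46,
                          baseline_hazard = 1 / 500,
                          censor_time_days = 2564,
                          seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients"),
    fraction_increased = assert_fraction(fraction_increased, "fraction_increased"),
    pre_clonotype_rate = assert_positive(pre_clonotype_rate, "pre_clonotype_rate"),
    post_clonotype_rate_increased =
      assert_positive(post_clonotype_rate_increased, "post_clonotype_rate_increased"),
    post_clonotype_rate_flat =
      assert_positive(post_clonotype_rate_flat, "post_clonotype_rate_flat"),
    tcr_clonotype_rate = assert_positive(tcr_clonotype_rate, "tcr_clonotype_rate"),
    clone_size_alpha = assert_positive(clone_size_alpha, "clone_size_alpha"),
    clone_size_max = assert_count(clone_size_max, "clone_size_max", min = 2),
    n_vgenes = assert_count(n_vgenes, "n_vgenes"),
    vgene_concentration = assert_positive(vgene_concentration, "vgene_concentration"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_cells_per_sample = assert_count(n_cells_per_sample, "n_cells_per_sample"),
    nb_mean = assert_positive(nb_mean, "nb_mean"),
    nb_dispersion = assert_positive(nb_dispersion, "nb_dispersion"),
    n_clusters = assert_count(n_clusters, "n_clusters"),
    marker_fold = assert_positive(marker_fold, "marker_fold"),
    planted_corr_genes = as.character(planted_corr_genes),
    planted_corr_cluster = planted_corr_cluster,
    planted_corr_strength = assert_fraction(planted_corr_strength, "planted_corr_strength"),
    spatial_field_um = assert_positive(spatial_field_um, "spatial_field_um"),
    n_cells_spatial = assert_count(n_cells_spatial, "n_cells_spatial"),
    proximity_radius_um = assert_positive(proximity_radius_um, "proximity_radius_um"),
    n_planted_pairs = assert_count(n_planted_pairs, "n_planted_pairs"),
    colocalization_rate = assert_fraction(colocalization_rate, "colocalization_rate"),
    triad_rate = assert_fraction(triad_rate, "triad_rate"),
    triad_types = as.character(triad_types),
    sharing_rate_colocalized =
      assert_fraction(sharing_rate_colocalized, "sharing_rate_colocalized"),
    sharing_rate_exclusive =
      assert_fraction(sharing_rate_exclusive, "sharing_rate_exclusive"),
    shared_expression_fold =
      assert_positive(shared_expression_fold, "shared_expression_fold"),
    hazard_ratio_increased =
      assert_positive(hazard_ratio_increased, "hazard_ratio_increased"),
    baseline_hazard = assert_positive(baseline_hazard, "baseline_hazard"),
    censor_time_days = assert_positive(censor_time_days, "censor_time_days"),
    seed = assert_count(seed, "seed", min = 0)
  )
  if (cfg$clone_size_alpha <= 1) {
    abort("`clone_size_alpha` must exceed 1.", class = "ct_config_error")
  }
  if (cfg$n_clusters > length(ct_cluster_names())) {
    abort(paste0("`n_clusters` must be <= ", length(ct_cluster_names()), "."),
          class = "ct_config_error")
  }
  if (length(cfg$triad_types) != 3L) {
    abort("`triad_types` must name exactly three cell types.",
          class = "ct_config_error")
  }
  if (cfg$proximity_radius_um > cfg$spatial_field_um) {
    abort("`proximity_radius_um` exceeds `spatial_field_um`.",
          class = "ct_config_error")
  }
  if (cfg$n_cells_spatial > (cfg$spatial_field_um^2) / 25) {
    abort("`n_cells_spatial` exceeds the spatial field capacity (one cell per 25 um^2).",
          class = "ct_generation_error")
  }
  if (2L * cfg$n_planted_pairs > cfg$n_vgenes) {
    abort("`n_vgenes` must be at least twice `n_planted_pairs`.",
          class = "ct_config_error")
  }
  structure(cfg, class = "ct_config")
}

#' @method print ct_config
#' @export
print.ct_config <- function(x, ...) {
  cat("<ct_config> synthetic cohort configuration\n")
  cat("  patients:", x$n_patients,
      sprintf("(%.0f%% planted increased)", 100 * x$fraction_increased), "\n")
  cat("  clonotype rates: pre", x$pre_clonotype_rate,
      "| post", x$post_clonotype_rate_increased, "/",
      x$post_clonotype_rate_flat, "(increased/flat)\n")
  cat("  expression:", x$n_genes, "genes x", x$n_cells_per_sample,
      "cells/sample,", x$n_clusters, "clusters\n")
  cat("  planted HR:", x$hazard_ratio_increased,
      "| censor at", x$censor_time_days, "days\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

ct_cluster_names <- function() {
  c("Activated CD8 T cell", "Exhausted CD8 T cell", "Memory CD8 T cell",
    "CD4 T cell", "Tfh", "B cell", "Plasma cell", "Malignant", "Fibroblast")
}

ct_vgene_universe <- function(locus, n) {
  prefix <- c(IGH = "IGHV", IGK = "IGKV", IGL = "IGLV",
              TRA = "TRAV", TRB = "TRBV")[[locus]]
  paste0(prefix, seq_len(n))
}

ct_gene_panel <- function(config) {
  named <- unique(c(config$planted_corr_genes, "MKI67", "CD69", "ENTPD1"))
  n_fill <- config$n_genes - length(named)
  if (n_fill < 0) {
    abort("`n_genes` smaller than the named marker gene set.",
          class = "ct_config_error")
  }
  c(named, sprintf("GENE%04d", seq_len(n_fill)))
}
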