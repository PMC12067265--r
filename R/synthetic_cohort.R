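#' Generate a synthetic immunotherapy cohort with planted ground truth
#'
#' Builds every input the pipeline consumes — AIRR-style clonotype tables,
#' a clustered cell-by-gene count matrix, spatial cell maps, and survival
#' records — from one seeded configuration, and returns the planted truth
#' alongside. Patients are split into an "increased" group (induced BCR
#' diversification: the post-treatment unique clonotype draw is conditioned
#' to exceed the pre-treatment draw) and a "flat" group; survival hazard,
#' the planted gene-diversity correlation, and the spatial structure all
#' key off that label.
#'
#' The generator runs on a hierarchical seed tree (cohort, then patient,
#' then sample) so that subsetting patients leaves every other patient's
#' draws untouched, and identical configurations reproduce byte-identical
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @param include which components to generate: any of `"repertoire"`,
#'   `"expression"`, `"spatial"`, `"survival"`. Skipping unused components
#'   keeps large simulation studies cheap.
#' @param n_spatial_patients number of patients receiving spatial maps
#'   (a treated lymph node, a treated tumor, and an untreated tumor each).
#' @return a `ct_cohort` list with elements `config`, `clonotypes`,
#'   `expression` (list: integer `counts` matrix, `cells`, `genes`),
#'   `spatial` (list of `ct_spatial_sample`), `survival`, and `truth`
#'   (planted labels, per-sample clonotype counts, realized planted
#'   correlations, V-gene usage, spatial truth, sharing truth, planted HR).
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 4, n_genes = 40, n_cells_per_sample = 50,
#'                      n_cells_spatial = 300, seed = 1)
#' coh <- generate_cohort(cfg, include = c("repertoire", "survival"))
#' head(coh$clonotypes)
#' coh$truth$labels
generate_cohort <- function(config,
                            include = c("repertoire", "expression",
                                        "spatial", "survival"),
                            n_spatial_patients = 2L) {
  stopifnot(inherits(config, "ct_config"))
  include <- match.arg(include, several.ok = TRUE)
  labels <- ct_patient_labels(config)
  counts <- ct_clonotype_counts(config, labels)
  usage <- ct_patient_usage(config, labels)

  cohort <- list(config = config, clonotypes = NULL, expression = NULL,
                 spatial = NULL, survival = NULL)
  truth <- list(
    labels = labels,
    sample_counts = counts,
    usage = usage,
    planted_hr = config$hazard_ratio_increased
  )

  if ("repertoire" %in% include) {
    cohort$clonotypes <- ct_repertoire(config, counts, usage)
  }
  if ("expression" %in% include) {
    expr <- ct_expression(config, counts)
    cohort$expression <- expr[c("counts", "cells", "genes")]
    truth$planted_corr <- expr$planted_corr
  }
  if ("survival" %in% include) {
    cohort$survival <- ct_survival(config, labels)
  }
  if ("spatial" %in% include) {
    sp <- ct_spatial(config, labels, usage,
                     n_spatial_patients = n_spatial_patients)
    cohort$spatial <- sp$samples
    truth$sharing <- sp$sharing
  }
  cohort$truth <- truth
  structure(cohort, class = "ct_cohort")
}

#' @method print ct_cohort
#' @export
print.ct_cohort <- function(x, ...) {
  cat("<ct_cohort>", x$config$n_patients, "patients, seed", x$config$seed, "\n")
  if (!is.null(x$clonotypes)) {
    cat("  clonotypes:", nrow(x$clonotypes), "chain records\n")
  }
  if (!is.null(x$expression)) {
    cat("  expression:", nrow(x$expression$counts), "cells x",
        ncol(x$expression$counts), "genes\n")
  }
  if (!is.null(x$spatial)) cat("  spatial maps:", length(x$spatial), "\n")
  if (!is.null(x$survival)) cat("  survival records:", nrow(x$survival), "\n")
  invisible(x)
}

# ---- planted labels and clonotype counts -----------------------------------

ct_patient_labels <- function(config) {
  ids <- sprintf("pt%03d", seq_len(config$n_patients))
  n_inc <- round(config$fraction_increased * config$n_patients)
  increased <- with_seed(mix_seed(config$seed, "labels"), {
    flags <- c(rep(TRUE, n_inc), rep(FALSE, config$n_patients - n_inc))
    sample(flags)
  })
  tibble::tibble(patient_id = ids, increased = increased)
}

# Post-treatment BCR clonotype counts are conditioned on the planted
# ordering (strict increase for "increased" patients, <= for "flat"), so the
# strict post > pre trajectory rule recovers the planted label exactly.
ct_clonotype_counts <- function(config, labels) {
  draw_post <- function(pre, rate, want_increase, seed) {
    with_seed(seed, {
      for (i in seq_len(1000L)) {
        post <- rpois(1L, rate)
        if ((want_increase && post > pre) || (!want_increase && post <= pre)) {
          return(post)
        }
      }
      if (want_increase) pre + 1L else pre # safeguard for extreme rates
    })
  }
  np <- nrow(labels)
  pre_bcr <- post_bcr <- integer(np)
  tcr <- matrix(0L, nrow = np, ncol = 2)
  for (i in seq_len(np)) {
    pid <- labels$patient_id[i]
    increased <- labels$increased[i]
    pseed <- mix_seed(config$seed, pid)
    pre_bcr[i] <- with_seed(mix_seed(pseed, "pre_bcr"),
                            rpois(1L, config$pre_clonotype_rate))
    rate <- if (increased) config$post_clonotype_rate_increased
            else config$post_clonotype_rate_flat
    post_bcr[i] <- draw_post(pre_bcr[i], rate, increased,
                             mix_seed(pseed, "post_bcr"))
    tcr[i, ] <- with_seed(mix_seed(pseed, "tcr"),
                          rpois(2L, config$tcr_clonotype_rate))
  }
  pid2 <- rep(labels$patient_id, each = 2L)
  tp2 <- rep(c("pre", "post"), np)
  tibble::tibble(
    patient_id = pid2,
    timepoint = tp2,
    sample_id = paste0(pid2, "_", tp2),
    n_bcr = as.integer(rbind(pre_bcr, post_bcr)),
    n_tcr = as.integer(t(tcr))
  )
}

# ---- V-gene usage -----------------------------------------------------------

rdirichlet1 <- function(n, concentration) {
  g <- rgamma(n, shape = concentration)
  if (sum(g) == 0) g <- rep(1, n)
  g / sum(g)
}

# IGH and TR usage are drawn once per patient-timepoint (shared across
# modalities and across the repertoire/spatial tables); light chains are
# drawn per sample elsewhere, so only the heavy chain carries a
# matched-sample fingerprint.
ct_patient_usage <- function(config, labels) {
  out <- list()
  for (pid in labels$patient_id) {
    for (tp in c("pre", "post")) {
      key <- paste0(pid, "_", tp)
      useed <- mix_seed(mix_seed(config$seed, pid), paste0("usage_", tp))
      out[[key]] <- with_seed(useed, list(
        IGH = setNames(rdirichlet1(config$n_vgenes, config$vgene_concentration),
                       ct_vgene_universe("IGH", config$n_vgenes)),
        TRA = setNames(rdirichlet1(config$n_vgenes, config$vgene_concentration),
                       ct_vgene_universe("TRA", config$n_vgenes)),
        TRB = setNames(rdirichlet1(config$n_vgenes, config$vgene_concentration),
                       ct_vgene_universe("TRB", config$n_vgenes))
      ))
    }
  }
  out
}

# ---- AIRR-style clonotype table --------------------------------------------

ct_repertoire <- function(config, counts, usage) {
  n_samples <- nrow(counts)
  acc <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    sample_id <- counts$sample_id[s]
    patient_id <- counts$patient_id[s]
    timepoint <- counts$timepoint[s]
    n_bcr <- counts$n_bcr[s]
    n_tcr <- counts$n_tcr[s]
    sseed <- mix_seed(mix_seed(config$seed, sample_id), "repertoire")
    acc[[s]] <- with_seed(sseed, {
      n_clones <- n_bcr + n_tcr
      if (n_clones == 0L) return(NULL)
      locus <- c(
        if (n_bcr > 0) sample(c("IGH", "IGK", "IGL"), n_bcr, replace = TRUE,
                              prob = c(0.6, 0.25, 0.15)),
        if (n_tcr > 0) sample(c("TRA", "TRB"), n_tcr, replace = TRUE)
      )
      key <- paste0(patient_id, "_", timepoint)
      light <- list(
        IGK = setNames(rdirichlet1(config$n_vgenes, config$vgene_concentration),
                       ct_vgene_universe("IGK", config$n_vgenes)),
        IGL = setNames(rdirichlet1(config$n_vgenes, config$vgene_concentration),
                       ct_vgene_universe("IGL", config$n_vgenes))
      )
      v_call <- character(n_clones)
      for (loc in unique(locus)) {
        idx <- which(locus == loc)
        p <- if (loc %in% c("IGK", "IGL")) light[[loc]] else usage[[key]][[loc]]
        v_call[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
      }
      jn <- random_junctions(n_clones, min_codons = 10, max_codons = 20)
      size <- rpowerlaw(n_clones, config$clone_size_alpha,
                        k_max = config$clone_size_max)
      expand <- rep.int(seq_len(n_clones), size)
      n_cells <- length(expand)
      list(
        cell_id = sprintf("%s_c%05d", sample_id, seq_len(n_cells)),
        sample_id = rep.int(sample_id, n_cells),
        patient_id = rep.int(patient_id, n_cells),
        timepoint = rep.int(timepoint, n_cells),
        locus = locus[expand],
        v_call = v_call[expand],
        junction = jn$junction[expand],
        junction_aa = jn$junction_aa[expand],
        duplicate_count = 1L + rpois(n_cells, 1)
      )
    })
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  cols <- c("cell_id", "sample_id", "patient_id", "timepoint", "locus",
            "v_call", "junction", "junction_aa", "duplicate_count")
  tibble::as_tibble(setNames(
    lapply(cols, function(cl) unlist(lapply(acc, `[[`, cl), use.names = FALSE)),
    cols))
}

# ---- expression -------------------------------------------------------------

ct_expression <- function(config, counts) {
  genes <- ct_gene_panel(config)
  clusters <- ct_cluster_names()[seq_len(config$n_clusters)]
  planted_cluster <- config$planted_corr_cluster
  plant_all <- !is.null(planted_cluster) && identical(planted_cluster, "all")
  if (!is.null(planted_cluster) && !plant_all &&
      !planted_cluster %in% clusters) {
    abort(paste0("`planted_corr_cluster` '", planted_cluster,
                 "' is not among the generated clusters."),
          class = "ct_config_error")
  }

  base_mean <- with_seed(mix_seed(config$seed, "gene_means"),
                         config$nb_mean * exp(rnorm(length(genes), 0, 0.5)))
  names(base_mean) <- genes

  # disjoint marker blocks: 5 filler genes per cluster, boosted marker_fold
  filler <- setdiff(genes, unique(c(config$planted_corr_genes,
                                    "MKI67", "CD69", "ENTPD1")))
  n_marker <- min(5L, max(0L, length(filler) %/% max(1L, length(clusters))))
  marker_map <- list()
  for (i in seq_along(clusters)) {
    marker_map[[clusters[i]]] <-
      filler[seq_len(n_marker) + (i - 1L) * n_marker]
  }

  # per-sample monotone shift of each planted gene: a latent variable
  # correlated planted_corr_strength with the standardized BCR count, with
  # independent sample-level noise per gene
  # the exponential link and count noise attenuate the latent correlation
  # by roughly 15% on the realized pseudobulk scale; the latent mix is
  # calibrated up so the realized correlation lands near the target
  r <- min(0.97, config$planted_corr_strength / 0.85)
  z <- as.numeric(scale(counts$n_bcr))
  if (any(!is.finite(z))) z <- rep(0, nrow(counts))
  n_pg <- length(config$planted_corr_genes)
  eta <- with_seed(mix_seed(config$seed, "planted_corr"), {
    eps <- matrix(rnorm(nrow(counts) * n_pg), nrow = nrow(counts))
    r * z + sqrt(max(0, 1 - r^2)) * eps
  })
  planted_factor <- exp(0.6 * eta) # samples x planted genes
  colnames(planted_factor) <- config$planted_corr_genes

  per_sample <- vector("list", nrow(counts))
  cell_meta <- vector("list", nrow(counts))
  for (s in seq_len(nrow(counts))) {
    sid <- counts$sample_id[s]
    sseed <- mix_seed(mix_seed(config$seed, sid), "expression")
    per_sample[[s]] <- with_seed(sseed, {
      n_cells <- config$n_cells_per_sample
      cl <- sample(clusters, n_cells, replace = TRUE)
      mu <- matrix(rep(base_mean, each = n_cells), nrow = n_cells,
                   dimnames = list(NULL, genes))
      for (cname in clusters) {
        rows <- cl == cname
        if (any(rows) && length(marker_map[[cname]])) {
          mu[rows, marker_map[[cname]]] <-
            mu[rows, marker_map[[cname]]] * config$marker_fold
        }
      }
      if (!is.null(planted_cluster) && length(config$planted_corr_genes)) {
        target_rows <- if (plant_all) rep(TRUE, n_cells) else cl == planted_cluster
        if (any(target_rows)) {
          mu[target_rows, config$planted_corr_genes] <-
            sweep(mu[target_rows, config$planted_corr_genes, drop = FALSE],
                  2, config$marker_fold * planted_factor[s, ], `*`)
        }
      }
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
                    nrow = n_cells, dimnames = list(NULL, genes))
      storage.mode(cnt) <- "integer"
      list(counts = cnt, cluster = cl)
    })
    cell_meta[[s]] <- tibble::tibble(
      cell_id = sprintf("%s_e%04d", sid, seq_len(config$n_cells_per_sample)),
      sample_id = sid,
      patient_id = counts$patient_id[s],
      timepoint = counts$timepoint[s],
      cluster = per_sample[[s]]$cluster
    )
  }
  mat <- do.call(rbind, lapply(per_sample, `[[`, "counts"))
  cells <- dplyr::bind_rows(cell_meta)
  rownames(mat) <- cells$cell_id

  # realized planted correlation, recorded in truth by direct arithmetic
  realized <- tibble::tibble(gene = character(), realized_r = numeric())
  if (!is.null(planted_cluster) && length(config$planted_corr_genes)) {
    # library sizes over the full panel, then log1p on the planted columns
    lib <- rowSums(mat)
    lib[lib == 0] <- 1
    norm <- log1p(sweep(mat[, config$planted_corr_genes, drop = FALSE],
                        1, 1e4 / lib, `*`))
    keep <- if (plant_all) rep(TRUE, nrow(cells)) else
      cells$cluster == planted_cluster
    realized <- purrr::map_dfr(config$planted_corr_genes, function(g) {
      v <- tapply(norm[keep, g], cells$sample_id[keep], mean)
      v <- v[counts$sample_id]
      tibble::tibble(gene = g,
                     realized_r = suppressWarnings(cor(v, counts$n_bcr)))
    })
  }
  list(counts = mat,
       cells = cells,
       genes = tibble::tibble(gene = genes,
                              base_mean = unname(base_mean)),
       planted_corr = list(genes = config$planted_corr_genes,
                           cluster = planted_cluster,
                           realized = realized))
}

# ---- survival ---------------------------------------------------------------

ct_survival <- function(config, labels) {
  t <- vapply(seq_len(nrow(labels)), function(i) {
    sseed <- mix_seed(mix_seed(config$seed, labels$patient_id[i]), "survival")
    rate <- config$baseline_hazard *
      config$hazard_ratio_increased^as.integer(labels$increased[i])
    with_seed(sseed, rexp(1L, rate))
  }, numeric(1))
  tibble::tibble(
    patient_id = labels$patient_id,
    time_days = pmin(t, config$censor_time_days),
    event = as.integer(t <= config$censor_time_days),
    group = ifelse(labels$increased, "increased", "flat")
  )
}
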