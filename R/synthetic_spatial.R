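#' Generate one synthetic spatial cell map
#'
#' Places background cells by complete spatial randomness on a square field
#' and, depending on treatment status and compartment, plants three kinds of
#' structure with recorded ground truth: (i) T/B pseudoclone colocalization —
#' for a fraction `colocalization_rate` of B cells of each planted pair's
#' IGH pseudoclone, a partner T cell of the paired TR pseudoclone is seeded
#' within the proximity radius (treated maps only); (ii) cell-type triads —
#' a fraction `triad_rate` of `triad_types[1]` cells anchor one cell of each
#' remaining triad type within the radius; (iii) per-cell V-gene probe
#' counts whose dominant gene follows the patient-timepoint usage spectrum.
#'
#' @param config a [cohort_config()].
#' @param sample_id identifier for the map.
#' @param treated logical; untreated maps never receive planted T/B pairs.
#' @param compartment `"tumor"` or `"lymph_node"` (drives cell-type mix).
#' @param patient_id optional patient identifier stored on the cells.
#' @param b_gene_pool,t_gene_pool IGH / TR V genes available for dominant
#'   assignment (default: the first `2 * n_planted_pairs` genes of each
#'   universe).
#' @param b_usage,t_usage optional named probability vectors over the full
#'   V-gene universes; renormalized over the pools. Defaults to a seeded
#'   Dirichlet draw.
#' @param planted_pairs tibble with columns `t_gene`, `b_gene` naming the
#'   pseudoclone pairs to colocalize; `NULL` for the default diagonal pairs.
#' @param plant_triads logical; defaults to lymph-node maps only.
#' @param elevated_t_genes TR V genes whose cells get
#'   `shared_expression_fold`-elevated MKI67/CD69/ENTPD1 counts (used by the
#'   cohort generator to mark compartment-shared clones).
#' @param seed integer seed (defaults to a child of the config seed).
#' @return a `ct_spatial_sample`: list with `sample_id`, `patient_id`,
#'   `compartment`, `treated`, `cells` (tibble with coordinates in
#'   micrometers, `cell_type`, one column per V-gene probe, and
#'   MKI67/CD69/ENTPD1 counts) and `truth` (list: `dominant` per-cell true
#'   dominant V genes, `planted_pairs`, `planted_triads`).
#' @export
generate_spatial_sample <- function(config, sample_id, treated,
                                    compartment = c("tumor", "lymph_node"),
                                    patient_id = NA_character_,
                                    b_gene_pool = NULL, t_gene_pool = NULL,
                                    b_usage = NULL, t_usage = NULL,
                                    planted_pairs = NULL,
                                    plant_triads = NULL,
                                    elevated_t_genes = character(),
                                    seed = NULL) {
  stopifnot(inherits(config, "ct_config"))
  compartment <- match.arg(compartment)
  assert_flag(treated, "treated")
  if (config$proximity_radius_um > config$spatial_field_um) {
    abort("Proximity radius exceeds the field side.", class = "ct_config_error")
  }
  if (is.null(seed)) seed <- mix_seed(config$seed, paste0("spatial_", sample_id))
  if (is.null(plant_triads)) plant_triads <- compartment == "lymph_node"

  igh_all <- ct_vgene_universe("IGH", config$n_vgenes)
  trb_all <- ct_vgene_universe("TRB", config$n_vgenes)
  np <- config$n_planted_pairs
  if (is.null(b_gene_pool)) b_gene_pool <- igh_all[seq_len(min(2L * np, length(igh_all)))]
  if (is.null(t_gene_pool)) t_gene_pool <- trb_all[seq_len(min(2L * np, length(trb_all)))]
  if (is.null(planted_pairs)) {
    planted_pairs <- tibble::tibble(t_gene = trb_all[seq_len(np)],
                                    b_gene = igh_all[seq_len(np)])
  }

  with_seed(seed, {
    if (is.null(b_usage)) {
      b_usage <- setNames(rdirichlet1(length(igh_all), config$vgene_concentration),
                          igh_all)
    }
    if (is.null(t_usage)) {
      t_usage <- setNames(rdirichlet1(length(trb_all), config$vgene_concentration),
                          trb_all)
    }
    renorm <- function(p, pool) {
      p <- p[pool]
      if (length(p) == 0 || sum(p) == 0) return(setNames(numeric(0), character(0)))
      p / sum(p)
    }
    b_p <- renorm(b_usage, b_gene_pool)
    t_p <- renorm(t_usage, t_gene_pool)

    comp <- ct_spatial_composition(compartment)
    n <- config$n_cells_spatial
    fld <- config$spatial_field_um
    cells <- tibble::tibble(
      x_um = runif(n, 0, fld),
      y_um = runif(n, 0, fld),
      cell_type = sample(names(comp), n, replace = TRUE, prob = comp)
    )

    t_types <- c("CD8 T cell", "Activated CD8 T cell", "CD4 T cell", "Tfh")
    is_b <- cells$cell_type == "B cell"
    is_t <- cells$cell_type %in% t_types
    dom <- rep(NA_character_, n)
    if (any(is_b) && length(b_p)) {
      dom[is_b] <- sample(names(b_p), sum(is_b), replace = TRUE, prob = b_p)
    }
    if (any(is_t) && length(t_p)) {
      dom[is_t] <- sample(names(t_p), sum(is_t), replace = TRUE, prob = t_p)
    }
    cells$.dom <- dom

    # planted T/B pseudoclone colocalization (treated maps only)
    pair_truth <- tibble::tibble(t_gene = character(), b_gene = character(),
                                 b_cell = character(), t_cell = character(),
                                 distance_um = numeric())
    extra <- list()
    if (treated && config$colocalization_rate > 0 && nrow(planted_pairs)) {
      for (k in seq_len(nrow(planted_pairs))) {
        bg <- planted_pairs$b_gene[k]
        tg <- planted_pairs$t_gene[k]
        if (!bg %in% names(b_p)) next
        members <- which(!is.na(cells$.dom) & cells$.dom == bg & is_b)
        if (!length(members)) next
        seeded <- members[runif(length(members)) < config$colocalization_rate]
        for (m in seeded) {
          pos <- runif_disc(cells$x_um[m], cells$y_um[m],
                            config$proximity_radius_um, fld)
          extra[[length(extra) + 1L]] <- tibble::tibble(
            x_um = pos[1], y_um = pos[2],
            cell_type = "Activated CD8 T cell", .dom = tg,
            .partner = m
          )
        }
      }
    }

    # planted triads around anchors of triad_types[1]
    triad_truth <- tibble::tibble(anchor = character(),
                                  member_2 = character(), member_3 = character())
    triad_extra <- list()
    if (plant_triads && config$triad_rate > 0) {
      anchors <- which(cells$cell_type == config$triad_types[1])
      anchors <- anchors[runif(length(anchors)) < config$triad_rate]
      for (a in anchors) {
        p2 <- runif_disc(cells$x_um[a], cells$y_um[a],
                         config$proximity_radius_um, fld)
        p3 <- runif_disc(cells$x_um[a], cells$y_um[a],
                         config$proximity_radius_um, fld)
        triad_extra[[length(triad_extra) + 1L]] <- tibble::tibble(
          x_um = c(p2[1], p3[1]), y_um = c(p2[2], p3[2]),
          cell_type = config$triad_types[2:3], .dom = NA_character_,
          .anchor = a
        )
      }
    }

    extra_tb <- dplyr::bind_rows(extra)
    triad_tb <- dplyr::bind_rows(triad_extra)
    all_cells <- dplyr::bind_rows(
      cells,
      if (nrow(extra_tb)) extra_tb[, c("x_um", "y_um", "cell_type", ".dom")],
      if (nrow(triad_tb)) triad_tb[, c("x_um", "y_um", "cell_type", ".dom")]
    )
    all_cells$cell_id <- sprintf("%s_s%05d", sample_id, seq_len(nrow(all_cells)))

    if (nrow(extra_tb)) {
      t_ids <- all_cells$cell_id[n + seq_len(nrow(extra_tb))]
      b_ids <- all_cells$cell_id[extra_tb$.partner]
      pair_truth <- tibble::tibble(
        t_gene = extra_tb$.dom,
        b_gene = all_cells$.dom[extra_tb$.partner],
        b_cell = b_ids, t_cell = t_ids,
        distance_um = sqrt((all_cells$x_um[extra_tb$.partner] - extra_tb$x_um)^2 +
                           (all_cells$y_um[extra_tb$.partner] - extra_tb$y_um)^2)
      )
    }
    if (nrow(triad_tb)) {
      idx0 <- n + (if (nrow(extra_tb)) nrow(extra_tb) else 0L)
      anc <- triad_tb$.anchor[seq(1, nrow(triad_tb), by = 2)]
      triad_truth <- tibble::tibble(
        anchor = all_cells$cell_id[anc],
        member_2 = all_cells$cell_id[idx0 + seq(1, nrow(triad_tb), by = 2)],
        member_3 = all_cells$cell_id[idx0 + seq(2, nrow(triad_tb), by = 2)]
      )
    }

    # V-gene probe counts: dominant gene gets 2 + Pois(3); one random
    # same-locus off-target gene gets Pois(0.4) noise
    m <- nrow(all_cells)
    probes <- matrix(0L, nrow = m, ncol = length(igh_all) + length(trb_all),
                     dimnames = list(NULL, c(igh_all, trb_all)))
    has_dom <- !is.na(all_cells$.dom)
    if (any(has_dom)) {
      di <- cbind(which(has_dom), match(all_cells$.dom[has_dom], colnames(probes)))
      probes[di] <- 2L + rpois(sum(has_dom), 3)
      side <- ifelse(all_cells$.dom[has_dom] %in% igh_all, "IGH", "TRB")
      noise_gene <- ifelse(side == "IGH",
                           sample(igh_all, sum(has_dom), replace = TRUE),
                           sample(trb_all, sum(has_dom), replace = TRUE))
      ni <- cbind(which(has_dom), match(noise_gene, colnames(probes)))
      keep <- noise_gene != all_cells$.dom[has_dom]
      probes[ni[keep, , drop = FALSE]] <- rpois(sum(keep), 0.4)
    }

    # expression probes used by the shared-vs-exclusive comparison
    expr_genes <- c("MKI67", "CD69", "ENTPD1")
    emu <- matrix(0.5, nrow = m, ncol = 3, dimnames = list(NULL, expr_genes))
    elev <- has_dom & all_cells$.dom %in% elevated_t_genes &
      all_cells$cell_type %in% t_types
    emu[elev, ] <- emu[elev, ] * config$shared_expression_fold
    expr <- matrix(rnbinom(length(emu), mu = emu, size = 2), nrow = m,
                   dimnames = list(NULL, expr_genes))
    storage.mode(expr) <- "integer"

    out_cells <- dplyr::bind_cols(
      tibble::tibble(cell_id = all_cells$cell_id,
                     x_um = all_cells$x_um, y_um = all_cells$y_um,
                     cell_type = all_cells$cell_type,
                     compartment = compartment, treated = treated),
      tibble::as_tibble(probes),
      tibble::as_tibble(expr)
    )
    structure(list(
      sample_id = sample_id,
      patient_id = patient_id,
      compartment = compartment,
      treated = treated,
      cells = out_cells,
      truth = list(
        dominant = tibble::tibble(
          cell_id = all_cells$cell_id[has_dom],
          locus_class = ifelse(all_cells$.dom[has_dom] %in% igh_all,
                               "IGH", "TCR"),
          v_gene = all_cells$.dom[has_dom]
        ),
        planted_pairs = pair_truth,
        planted_triads = triad_truth
      )
    ), class = "ct_spatial_sample")
  })
}

#' @method print ct_spatial_sample
#' @export
print.ct_spatial_sample <- function(x, ...) {
  cat("<ct_spatial_sample>", x$sample_id, "-", x$compartment,
      if (isTRUE(x$treated)) "(treated)" else "(untreated)", "\n")
  cat(" ", nrow(x$cells), "cells;", nrow(x$truth$planted_pairs),
      "planted T/B pair links;", nrow(x$truth$planted_triads),
      "planted triads\n")
  invisible(x)
}

# uniform point in the disc of radius r around (x, y), clipped to the field
runif_disc <- function(x, y, r, field) {
  theta <- runif(1, 0, 2 * pi)
  rad <- r * sqrt(runif(1))
  c(min(max(x + rad * cos(theta), 0), field),
    min(max(y + rad * sin(theta), 0), field))
}

ct_spatial_composition <- function(compartment) {
  if (compartment == "tumor") {
    c("Malignant" = 0.30, "Keratinocyte" = 0.15, "Fibroblast" = 0.10,
      "B cell" = 0.12, "CD8 T cell" = 0.12, "Activated CD8 T cell" = 0.06,
      "CD4 T cell" = 0.08, "Tfh" = 0.03, "Dendritic cell" = 0.04)
  } else {
    c("B cell" = 0.30, "CD4 T cell" = 0.15, "CD8 T cell" = 0.15,
      "Activated CD8 T cell" = 0.08, "Tfh" = 0.10, "Dendritic cell" = 0.07,
      "Fibroblast" = 0.10, "Keratinocyte" = 0.05, "Malignant" = 0.00)
  }
}

# Cohort-level spatial coordination: for each spatial patient, one treated
# lymph-node map, one treated tumor map, and one untreated tumor map. Clone
# sharing between lymph node and tumor is planted at the pair level:
# colocalized (diagonal planted) pairs carry both genes into the tumor with
# probability sharing_rate_colocalized; every other lymph-node V gene enters
# the tumor independently at sharing_rate_exclusive.
ct_spatial <- function(config, labels, usage, n_spatial_patients = 2L) {
  pts <- head(labels$patient_id, n_spatial_patients)
  igh_all <- ct_vgene_universe("IGH", config$n_vgenes)
  trb_all <- ct_vgene_universe("TRB", config$n_vgenes)
  np <- config$n_planted_pairs
  diag_pairs <- tibble::tibble(t_gene = trb_all[seq_len(np)],
                               b_gene = igh_all[seq_len(np)])
  b_pool_ln <- igh_all[seq_len(2L * np)]
  t_pool_ln <- trb_all[seq_len(2L * np)]

  samples <- list()
  sharing <- list()
  for (pid in pts) {
    pseed <- mix_seed(mix_seed(config$seed, pid), "sharing")
    draws <- with_seed(pseed, {
      list(pair_shared = runif(np) < config$sharing_rate_colocalized,
           gene_extra_b = runif(2L * np) < config$sharing_rate_exclusive,
           gene_extra_t = runif(2L * np) < config$sharing_rate_exclusive)
    })
    tumor_b <- unique(c(diag_pairs$b_gene[draws$pair_shared],
                        b_pool_ln[draws$gene_extra_b]))
    tumor_t <- unique(c(diag_pairs$t_gene[draws$pair_shared],
                        t_pool_ln[draws$gene_extra_t]))
    shared_t_genes <- diag_pairs$t_gene[draws$pair_shared]
    key <- paste0(pid, "_post")
    b_usage <- usage[[key]]$IGH
    t_usage <- usage[[key]]$TRB

    ln <- generate_spatial_sample(
      config, sample_id = paste0(pid, "_ln_post"), treated = TRUE,
      compartment = "lymph_node", patient_id = pid,
      b_gene_pool = b_pool_ln, t_gene_pool = t_pool_ln,
      b_usage = b_usage, t_usage = t_usage,
      planted_pairs = diag_pairs, plant_triads = TRUE,
      elevated_t_genes = shared_t_genes
    )
    tum_post <- generate_spatial_sample(
      config, sample_id = paste0(pid, "_tumor_post"), treated = TRUE,
      compartment = "tumor", patient_id = pid,
      b_gene_pool = tumor_b, t_gene_pool = tumor_t,
      b_usage = b_usage, t_usage = t_usage,
      planted_pairs = diag_pairs[draws$pair_shared, , drop = FALSE],
      plant_triads = FALSE,
      elevated_t_genes = shared_t_genes
    )
    tum_pre <- generate_spatial_sample(
      config, sample_id = paste0(pid, "_tumor_pre"), treated = FALSE,
      compartment = "tumor", patient_id = pid,
      b_gene_pool = b_pool_ln, t_gene_pool = t_pool_ln,
      b_usage = usage[[paste0(pid, "_pre")]]$IGH,
      t_usage = usage[[paste0(pid, "_pre")]]$TRB,
      planted_pairs = diag_pairs, plant_triads = FALSE
    )
    samples[[ln$sample_id]] <- ln
    samples[[tum_post$sample_id]] <- tum_post
    samples[[tum_pre$sample_id]] <- tum_pre
    sharing[[pid]] <- tibble::tibble(
      patient_id = pid,
      t_gene = diag_pairs$t_gene, b_gene = diag_pairs$b_gene,
      colocalized_planted = TRUE,
      shared_planted = draws$pair_shared
    )
  }
  list(samples = samples, sharing = dplyr::bind_rows(sharing))
}
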