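test_that("proximity graph equals the all-pairs oracle, inclusive at the boundary", {
  exact <- tibble::tibble(cell_id = c("a", "b"), x_um = c(0, 20), y_um = 0,
                          cell_type = "A")
  g <- proximity_graph(exact, radius_um = 20)
  expect_equal(nrow(g), 1L)
  expect_equal(g$distance_um, 20)

  lone <- proximity_graph(exact[1, ], radius_um = 20)
  expect_equal(nrow(lone), 0L)

  cells <- random_map(500, field = 250, seed = 4)
  got <- proximity_graph(cells, radius_um = 20) |>
    dplyr::arrange(cell_a, cell_b)
  orc <- oracle_proximity(cells, 20) |>
    dplyr::arrange(cell_a, cell_b)
  expect_equal(got$cell_a, orc$cell_a)
  expect_equal(got$cell_b, orc$cell_b)
  expect_equal(got$distance_um, orc$distance_um, tolerance = 1e-12)
})

test_that("pseudoclone assignment follows max count with lexicographic ties", {
  cells <- tibble::tibble(
    cell_id = c("b1", "b2", "b3", "t1", "k1"),
    x_um = 1:5, y_um = 1,
    cell_type = c("B cell", "B cell", "B cell", "CD8 T cell", "Malignant"),
    `IGHV1-2` = c(3L, 2L, 0L, 0L, 5L),
    `IGHV3-23` = c(0L, 2L, 0L, 0L, 0L),
    TRBV5 = c(0L, 0L, 0L, 4L, 0L))
  expect_warning(a <- assign_pseudoclones(cells, "IGH"), "skipped")
  expect_equal(a$v_gene[a$cell_id == "b1"], "IGHV1-2")
  # tie broken toward the lexicographically first gene
  expect_equal(a$v_gene[a$cell_id == "b2"], "IGHV1-2")
  # all-zero cells unassigned
  expect_false("b3" %in% a$cell_id)
  # wrong lineage (malignant with IGH counts) skipped
  expect_false("k1" %in% a$cell_id)

  t_assign <- assign_pseudoclones(cells, "TCR")
  expect_equal(t_assign$cell_id, "t1")

  # sizes sum to the number of assigned cells
  sizes <- pseudoclone_sizes(a)
  expect_equal(sum(sizes$size), nrow(a))
})

test_that("assignments recover the generator's planted dominant genes", {
  cfg <- cohort_config(n_cells_spatial = 1200, seed = 61)
  sp <- generate_spatial_sample(cfg, "m1", treated = TRUE,
                                compartment = "lymph_node")
  for (lc in c("IGH", "TCR")) {
    a <- suppressWarnings(assign_pseudoclones(sp$cells, lc))
    tr <- dplyr::filter(sp$truth$dominant, locus_class == lc)
    m <- dplyr::inner_join(a, tr, by = "cell_id")
    expect_gt(nrow(m), 50)
    expect_gte(mean(m$v_gene.x == m$v_gene.y), 0.95)
  }
})

test_that("neighborhood enrichment is calibrated on CSR and flags degenerate input", {
  cells <- random_map(600, field = 400, types = c("A", "B", "bg"),
                      probs = c(0.2, 0.2, 0.6), seed = 9)
  res <- neighborhood_enrichment(cells, "A", "B", radius_um = 20,
                                 n_permutations = 200, seed = 1)
  expect_false(res$undefined)
  expect_lt(abs(res$z), 3)

  none <- neighborhood_enrichment(cells, "A", "Z", n_permutations = 100)
  expect_true(none$undefined)

  lone <- tibble::tibble(cell_id = c("x", "y"), x_um = c(0, 5), y_um = 0,
                         cell_type = c("A", "bg"))
  solo <- neighborhood_enrichment(lone, "A", "A", n_permutations = 100)
  expect_true(solo$undefined)

  expect_error(neighborhood_enrichment(cells, "A", "B", n_permutations = 10),
               class = "ct_config_error")
})

test_that("enrichment z is invariant to rigid motions of the coordinates", {
  cells <- random_map(400, field = 300, types = c("A", "B", "bg"), seed = 12)
  base <- neighborhood_enrichment(cells, "A", "B", n_permutations = 150,
                                  seed = 3)
  th <- 0.7
  moved <- dplyr::mutate(cells,
                         x2 = cos(th) * x_um - sin(th) * y_um + 100,
                         y2 = sin(th) * x_um + cos(th) * y_um - 40,
                         x_um = x2, y_um = y2)
  rot <- neighborhood_enrichment(moved, "A", "B", n_permutations = 150,
                                 seed = 3)
  expect_equal(rot$z, base$z, tolerance = 1e-12)
  expect_equal(rot$n_observed, base$n_observed)
})

test_that("planted T/B colocalization is detected and absent in untreated maps", {
  cfg <- cohort_config(n_cells_spatial = 1200, colocalization_rate = 0.8,
                       seed = 62)
  treated <- generate_spatial_sample(cfg, "tr", treated = TRUE,
                                     compartment = "lymph_node")
  co <- pseudoclone_colocalization(treated$cells, n_permutations = 200,
                                   seed = 5)
  planted <- dplyr::semi_join(
    co, dplyr::distinct(treated$truth$planted_pairs, t_gene, b_gene),
    by = c("t_gene", "b_gene"))
  expect_gt(nrow(planted), 0)
  expect_gt(min(planted$z), 3)

  untreated <- generate_spatial_sample(cfg, "un", treated = FALSE,
                                       compartment = "lymph_node")
  co_un <- pseudoclone_colocalization(untreated$cells, n_permutations = 200,
                                      seed = 5)
  expect_lt(mean(co_un$colocalized, na.rm = TRUE), 0.1)
})

test_that("size correlation appears only in the treated colocalized stratum", {
  cfg <- cohort_config(n_cells_spatial = 1500, colocalization_rate = 0.5,
                       seed = 63)
  pair_tb <- dplyr::bind_rows(lapply(1:4, function(k) {
    tr <- generate_spatial_sample(cfg, paste0("tr", k), treated = TRUE,
                                  compartment = "lymph_node",
                                  seed = 990 + k)
    un <- generate_spatial_sample(cfg, paste0("un", k), treated = FALSE,
                                  compartment = "lymph_node",
                                  seed = 1990 + k)
    dplyr::bind_rows(
      dplyr::mutate(pseudoclone_colocalization(tr$cells,
                                               n_permutations = 150,
                                               seed = k), treated = TRUE),
      dplyr::mutate(pseudoclone_colocalization(un$cells,
                                               n_permutations = 150,
                                               seed = k), treated = FALSE))
  }))
  strata <- size_correlation_by_colocalization(pair_tb)
  rho_tc <- strata$rho[strata$treated & strata$colocalized]
  expect_gt(rho_tc, 0.3)
  rho_un <- strata$rho[!strata$treated & !strata$colocalized]
  expect_lt(abs(rho_un), 0.25)

  # all-identical sizes on one side: undefined
  flat <- tibble::tibble(treated = TRUE, colocalized = TRUE,
                         t_size = c(1, 2, 3, 4), b_size = 2)
  expect_true(is.na(size_correlation_by_colocalization(flat)$rho))
})

test_that("compartment sharing has exact limits and recovers the planted ratio regime", {
  co <- tibble::tibble(t_gene = paste0("TRBV", 1:6),
                       b_gene = paste0("IGHV", 1:6),
                       colocalized = rep(c(TRUE, FALSE), each = 3))
  # tumor detects none of the lymph-node genes
  tum_none <- tibble::tibble(cell_id = "x", x_um = 1, y_um = 1,
                             cell_type = "B cell", IGHV99 = 1L, TRBV99 = 0L)
  sh0 <- shared_pair_fraction(co, tum_none)
  expect_equal(sh0$fraction_shared_colocalized, 0)
  expect_equal(sh0$fraction_shared_noncolocalized, 0)

  # tumor detects every pair: both fractions 1, ratio 1
  tum_all <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(cell_id = paste0(c("b", "t"), i), x_um = i, y_um = i,
                   cell_type = c("B cell", "CD8 T cell"))
  }))
  for (i in 1:6) {
    tum_all[[paste0("IGHV", i)]] <- as.integer(tum_all$cell_id == paste0("b", i))
    tum_all[[paste0("TRBV", i)]] <- as.integer(tum_all$cell_id == paste0("t", i))
  }
  sh1 <- shared_pair_fraction(co, tum_all)
  expect_equal(sh1$fraction_shared_colocalized, 1)
  expect_equal(sh1$ratio, 1)

  expect_error(shared_pair_fraction(co[0, ], tum_all),
               class = "ct_undefined_error")
})

test_that("shared clones show the planted expression elevation", {
  cfg <- cohort_config(n_cells_spatial = 1500, shared_expression_fold = 2,
                       sharing_rate_colocalized = 0.5, seed = 64)
  coh <- generate_cohort(cfg, include = "spatial", n_spatial_patients = 1)
  both <- dplyr::bind_rows(coh$spatial[["pt001_ln_post"]]$cells,
                           coh$spatial[["pt001_tumor_post"]]$cells)
  res <- suppressWarnings(shared_vs_exclusive_expression(both))
  mki <- dplyr::filter(res, gene == "MKI67", !skipped)
  expect_gt(nrow(mki), 0)
  expect_true(all(mki$effect > 0))
  expect_lt(min(mki$p_value), 0.01)

  missing <- suppressWarnings(
    shared_vs_exclusive_expression(both, genes = "NOTAGENE"))
  expect_true(all(missing$skipped))
})
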