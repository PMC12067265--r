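test_that("identical configuration and seed reproduce byte-identical cohorts", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL, version = 2),
                   serialize(b, NULL, version = 2))
})

test_that("planted labels follow the configured fraction and conditioning", {
  cfg <- small_config(fraction_increased = 1)
  coh <- generate_cohort(cfg, include = "repertoire")
  expect_true(all(coh$truth$labels$increased))

  cfg2 <- small_config(n_patients = 20, fraction_increased = 0.5)
  coh2 <- generate_cohort(cfg2, include = "repertoire")
  expect_equal(sum(coh2$truth$labels$increased), 10)
  # the post draw is conditioned on the planted ordering
  wide <- tidyr::pivot_wider(coh2$truth$sample_counts,
                             id_cols = "patient_id",
                             names_from = "timepoint",
                             values_from = "n_bcr")
  inc <- coh2$truth$labels$increased[match(wide$patient_id,
                                           coh2$truth$labels$patient_id)]
  expect_true(all(wide$post[inc] > wide$pre[inc]))
  expect_true(all(wide$post[!inc] <= wide$pre[!inc]))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(cohort_config(fraction_increased = 1.4), "fraction_increased",
               class = "ct_config_error")
  expect_error(cohort_config(nb_mean = -1), "nb_mean",
               class = "ct_config_error")
  expect_error(cohort_config(n_patients = 0), "n_patients",
               class = "ct_config_error")
  expect_error(cohort_config(clone_size_alpha = 0.8),
               class = "ct_config_error")
  expect_error(cohort_config(n_cells_spatial = 1e6, spatial_field_um = 100),
               class = "ct_generation_error")
})

test_that("the patient seed tree isolates patients from cohort subsetting", {
  c5 <- generate_cohort(small_config(n_patients = 5), include = "repertoire")
  c3 <- generate_cohort(small_config(n_patients = 3), include = "repertoire")
  pick <- function(coh) dplyr::filter(coh$clonotypes, patient_id == "pt002")
  expect_identical(pick(c5), pick(c3))
})

test_that("clone sizes follow the configured truncated power law", {
  sizes <- withr::with_seed(7, rpowerlaw(1e5, alpha = 2.5, k_max = 1000))
  alpha_hat <- fit_powerlaw_exponent(sizes, k_max = 1000)
  expect_lt(abs(alpha_hat - 2.5), 0.1)
  sizes2 <- withr::with_seed(8, rpowerlaw(1e5, alpha = 3.2, k_max = 1000))
  expect_lt(abs(fit_powerlaw_exponent(sizes2, k_max = 1000) - 3.2), 0.1)
})

test_that("expression marginals are overdispersed negative binomial", {
  cfg <- small_config(n_patients = 6, n_genes = 60, n_cells_per_sample = 150)
  coh <- generate_cohort(cfg, include = c("repertoire", "expression"))
  m <- coh$expression$counts
  gm <- colMeans(m)
  gv <- apply(m, 2, var)
  keep <- gm > 0.2
  expect_gt(mean(gv[keep] > gm[keep]), 0.9)
})

test_that("flat-group survival is shorter than increased-group survival under HR < 1", {
  cfg <- cohort_config(n_patients = 400, hazard_ratio_increased = 0.46,
                       seed = 11)
  coh <- generate_cohort(cfg, include = "survival")
  km <- km_estimate(coh$survival)
  med <- function(g) {
    k <- dplyr::filter(km, group == g, survival <= 0.5)
    min(k$time)
  }
  expect_lt(med("flat"), med("increased"))
})

test_that("every sample in generated tables exists in cohort metadata and ids are unique", {
  cfg <- small_config()
  coh <- generate_cohort(cfg)
  samples <- coh$truth$sample_counts$sample_id
  expect_true(all(coh$clonotypes$sample_id %in% samples))
  expect_true(all(coh$expression$cells$sample_id %in% samples))
  expect_false(any(duplicated(coh$expression$cells$cell_id)))
  for (sp in coh$spatial) {
    expect_false(any(duplicated(sp$cells$cell_id)))
  }
})

test_that("cohorts round-trip through the on-disk formats", {
  cfg <- small_config(n_patients = 2)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)

  airr <- read_airr(file.path(dir, "clonotypes.tsv"))
  expect_equal(nrow(airr), nrow(coh$clonotypes))
  expect_equal(count_unique_clonotypes(airr, "BCR"),
               count_unique_clonotypes(coh$clonotypes, "BCR"))

  expr <- read_expression(dir)
  expect_equal(unname(expr$counts), unname(coh$expression$counts))
  expect_equal(expr$cells$cluster, coh$expression$cells$cluster)

  surv <- read_survival(file.path(dir, "survival.csv"))
  expect_equal(surv$time_days, coh$survival$time_days)

  sp_file <- list.files(dir, pattern = "^spatial_.*csv$", full.names = TRUE)[1]
  sp <- read_spatial_cells(sp_file)
  expect_true(all(c("cell_id", "x_um", "y_um", "cell_type") %in% names(sp)))

  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$planted_hr, cfg$hazard_ratio_increased)
})

test_that("AIRR parsing rejects malformed tables with row-level errors", {
  dir <- withr::local_tempdir()
  bad <- toy_clonotypes(loci = c("IGH", "XXX"), v_calls = c("IGHV1", "IGHV2"),
                        junctions = c("TGTAAA", "TGTCCC"))
  readr::write_tsv(bad, file.path(dir, "bad.tsv"))
  expect_error(read_airr(file.path(dir, "bad.tsv")), "row",
               class = "ct_parse_error")
  empty_j <- toy_clonotypes(loci = c("IGH"), v_calls = "IGHV1", junctions = "")
  expect_error(validate_clonotypes(empty_j), class = "ct_parse_error")
  readr::write_tsv(bad[, c("cell_id", "locus")], file.path(dir, "cols.tsv"))
  expect_error(read_airr(file.path(dir, "cols.tsv")), "required",
               class = "ct_parse_error")
})

test_that("untreated spatial maps carry no planted pairs and rates can be zeroed", {
  cfg <- small_config(colocalization_rate = 0, triad_rate = 0)
  sp <- generate_spatial_sample(cfg, "zero", treated = TRUE,
                                compartment = "lymph_node")
  expect_equal(nrow(sp$truth$planted_pairs), 0)
  expect_equal(nrow(sp$truth$planted_triads), 0)

  cfg2 <- small_config(colocalization_rate = 0.8)
  sp2 <- generate_spatial_sample(cfg2, "untreated", treated = FALSE,
                                 compartment = "tumor")
  expect_equal(nrow(sp2$truth$planted_pairs), 0)
})

test_that("planted pair members lie within the proximity radius", {
  cfg <- cohort_config(n_cells_spatial = 1200, seed = 19)
  sp <- generate_spatial_sample(cfg, "pl", treated = TRUE,
                                compartment = "lymph_node")
  tr <- sp$truth$planted_pairs
  expect_gt(nrow(tr), 0)
  xy <- sp$cells[match(c(tr$b_cell, tr$t_cell), sp$cells$cell_id), ]
  n <- nrow(tr)
  d <- sqrt((xy$x_um[1:n] - xy$x_um[n + 1:n])^2 +
            (xy$y_um[1:n] - xy$y_um[n + 1:n])^2)
  expect_true(all(d <= cfg$proximity_radius_um + 1e-9))
  expect_equal(d, tr$distance_um, tolerance = 1e-9)
})
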