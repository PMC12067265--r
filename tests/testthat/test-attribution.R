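toy_expression <- function() {
  # 3 samples x 2 clusters x 2 cells, 3 genes
  cells <- tidyr::expand_grid(sample_id = c("s1", "s2", "s3"),
                              cluster = c("K1", "K2"),
                              rep = 1:2) |>
    dplyr::mutate(cell_id = sprintf("%s_%s_%d", sample_id, cluster, rep))
  m <- matrix(rpois(nrow(cells) * 3, 5), nrow = nrow(cells),
              dimnames = list(cells$cell_id, c("g1", "g2", "g3")))
  list(counts = m, cells = cells)
}

test_that("pseudobulk averages normalized cells with hand-checkable arithmetic", {
  cells <- tibble::tibble(cell_id = c("a", "b"), sample_id = "s1",
                          cluster = "K1")
  counts <- matrix(c(0, 4, 10, 6), nrow = 2,
                   dimnames = list(c("a", "b"), c("g1", "g2")))
  prof <- pseudobulk(counts, cells, scale_to = 10)
  # cell a: lib 10 -> g1 log1p(0); cell b: lib 10 -> g1 log1p(4)
  expect_equal(prof$g1, mean(c(log1p(0), log1p(4))))
  expect_equal(prof$g2, mean(c(log1p(10), log1p(6))))
  expect_equal(prof$cells_used, 2L)
})

test_that("blinding a label with zero cells is a no-op; blinding everything drops the sample", {
  set.seed(21)
  toy <- toy_expression()
  meta <- dplyr::mutate(toy$cells,
                        cluster = factor(cluster, levels = c("K1", "K2", "K9")))
  full <- pseudobulk(toy$counts, meta)
  noop <- pseudobulk(toy$counts, meta, blind_cluster = "K9")
  expect_equal(full, noop, ignore_attr = TRUE)
  expect_error(pseudobulk(toy$counts, meta, blind_cluster = "nope"),
               class = "ct_input_error")

  only <- dplyr::mutate(toy$cells, cluster = "K1")
  dropped <- pseudobulk(toy$counts, only, blind_cluster = "K1")
  expect_equal(nrow(dropped), 0)
  expect_setequal(attr(dropped, "dropped_samples"), c("s1", "s2", "s3"))
})

test_that("gene-diversity correlation flags zero variance and recovers exact linearity", {
  set.seed(22)
  n <- 8
  bcr <- tibble::tibble(sample_id = paste0("s", 1:n),
                        n_unique = c(5, 9, 14, 20, 26, 31, 38, 44))
  prof <- tibble::tibble(sample_id = bcr$sample_id, cells_used = 10L,
                         flat = rep(2, n),
                         affine = 0.3 + 0.05 * bcr$n_unique,
                         noise = rnorm(n))
  res <- gene_diversity_correlation(prof, bcr)
  expect_true(res$zero_variance[res$gene == "flat"])
  expect_true(is.na(res$r[res$gene == "flat"]))
  expect_equal(res$r[res$gene == "affine"], 1, tolerance = 1e-12)
  expect_error(gene_diversity_correlation(prof[1:3, ], bcr),
               class = "ct_input_error")

  # agreement with an independent streaming implementation
  r_stream <- oracle_streaming_pearson(prof$noise, bcr$n_unique)
  expect_equal(res$r[res$gene == "noise"], r_stream, tolerance = 1e-10)

  # BH q-values are monotone in the rank of p
  ord <- order(res$p[!res$zero_variance])
  qs <- res$q[!res$zero_variance][ord]
  expect_true(all(diff(qs) >= -1e-12))
})

test_that("cluster blinding attributes a planted confined signal to its cluster", {
  cfg <- cohort_config(n_patients = 15, seed = 51)
  coh <- generate_cohort(cfg, include = c("repertoire", "expression"))
  cnt <- count_unique_clonotypes(coh$clonotypes, "BCR")
  res <- cluster_blinding_delta(coh$expression$counts, coh$expression$cells,
                                cnt, genes = cfg$planted_corr_genes)
  loc <- res$delta |>
    dplyr::group_by(gene) |>
    dplyr::slice_max(delta, n = 1, with_ties = FALSE)
  # most planted genes localize on a single cohort; the replicate-level
  # recovery rate is exercised at larger scale in the acceptance suite
  expect_gte(mean(loc$cluster == cfg$planted_corr_cluster), 2 / 3)
  other <- dplyr::filter(res$delta, cluster != cfg$planted_corr_cluster)
  expect_lt(max(abs(other$delta)), 0.15)
  # recovered correlation near the generator's realized planted value
  base <- dplyr::filter(res$base, gene %in% cfg$planted_corr_genes)
  realized <- coh$truth$planted_corr$realized
  m <- dplyr::inner_join(base, realized, by = "gene")
  expect_lt(max(abs(m$r - m$realized_r)), 0.2)
  # cluster sizes reported for every cluster
  expect_setequal(res$cluster_sizes$cluster,
                  unique(coh$expression$cells$cluster))
})

test_that("a signal planted uniformly over clusters yields no attribution", {
  cfg <- cohort_config(n_patients = 15, planted_corr_cluster = "all",
                       seed = 52)
  coh <- generate_cohort(cfg, include = c("repertoire", "expression"))
  cnt <- count_unique_clonotypes(coh$clonotypes, "BCR")
  res <- cluster_blinding_delta(coh$expression$counts, coh$expression$cells,
                                cnt, genes = cfg$planted_corr_genes)
  expect_lt(max(abs(res$delta$delta)), 0.15)
})

test_that("display gene selection is disjoint, deterministic, and tie-stable", {
  set.seed(23)
  base <- tibble::tibble(gene = sprintf("G%03d", 1:480),
                         r = runif(480, -1, 1), p = runif(480),
                         q = runif(480), n_samples = 30,
                         zero_variance = FALSE)
  sel <- select_display_genes(base, k = 25, seed = 9)
  expect_equal(lengths(sel), c(top = 25L, random = 25L, bottom = 25L))
  expect_equal(length(unique(unlist(sel))), 75L)
  expect_equal(sel$top, base$gene[order(-base$r)][1:25])
  sel2 <- select_display_genes(base, k = 25, seed = 9)
  expect_identical(sel, sel2)
  sel3 <- select_display_genes(base, k = 25, seed = 10)
  expect_false(identical(sel3$random, sel$random))

  ties <- dplyr::mutate(base, r = 0.5)
  selt <- select_display_genes(ties, k = 25, seed = 1)
  expect_equal(selt$top, sort(ties$gene)[1:25])
  expect_equal(length(intersect(selt$top, selt$bottom)), 0L)

  expect_error(select_display_genes(base[1:50, ], k = 25),
               class = "ct_input_error")
})
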