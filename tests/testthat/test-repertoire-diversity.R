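test_that("unique clonotype counting keys on locus, V gene and junction", {
  rec <- toy_clonotypes(
    loci = rep("IGH", 5),
    v_calls = c("IGHV1", "IGHV1", "IGHV2", "IGHV2", "IGHV3"),
    junctions = c("TGTAAA", "TGTAAA", "TGTCCC", "TGTCCC", "TGTGGG"))
  expect_equal(count_unique_clonotypes(rec, "BCR")$n_unique, 3L)
  expect_equal(count_unique_clonotypes(rec, "TCR")$n_unique, 0L)

  # same key at a different locus is a different clonotype
  rec2 <- dplyr::bind_rows(rec,
    toy_clonotypes(loci = "IGK", v_calls = "IGHV1", junctions = "TGTAAA",
                   cell_ids = "c9"))
  expect_equal(count_unique_clonotypes(rec2, "BCR")$n_unique, 4L)

  empty <- rec[0, ]
  expect_equal(nrow(count_unique_clonotypes(empty, "BCR")), 0L)
})

test_that("counting is permutation-invariant and monotone under addition", {
  cfg <- small_config()
  coh <- generate_cohort(cfg, include = "repertoire")
  rec <- coh$clonotypes
  shuffled <- rec[withr::with_seed(1, sample(nrow(rec))), ]
  a <- count_unique_clonotypes(rec, "BCR")
  b <- count_unique_clonotypes(shuffled, "BCR")
  expect_equal(dplyr::arrange(a, sample_id), dplyr::arrange(b, sample_id))

  sub <- rec[seq_len(nrow(rec) %/% 2), ]
  asub <- count_unique_clonotypes(sub, "BCR")
  joined <- dplyr::inner_join(asub, a, by = "sample_id",
                              suffix = c("_sub", "_full"))
  expect_true(all(joined$n_unique_sub <= joined$n_unique_full))
})

test_that("synthetic counts match the generator's planted distinct keys exactly", {
  coh <- generate_cohort(small_config(n_patients = 6), include = "repertoire")
  got <- count_unique_clonotypes(coh$clonotypes, "BCR")
  truth <- coh$truth$sample_counts
  m <- dplyr::inner_join(got, truth, by = "sample_id")
  expect_equal(m$n_unique, m$n_bcr)
  got_t <- count_unique_clonotypes(coh$clonotypes, "TCR")
  m_t <- dplyr::inner_join(got_t, truth, by = "sample_id")
  expect_equal(m_t$n_unique, m_t$n_tcr)
})

test_that("the dominant-chain filter keeps one deterministic record per cell-locus", {
  rec <- toy_clonotypes(
    loci = rep("IGH", 3), v_calls = c("IGHV1", "IGHV2", "IGHV3"),
    junctions = c("TGTCCC", "TGTAAA", "TGTGGG"),
    cell_ids = c("c1", "c1", "c1"), dup = c(5L, 5L, 2L))
  kept <- dominant_chain_filter(rec)
  expect_equal(nrow(kept), 1L)
  # ties on duplicate_count break on lexicographically smallest junction
  expect_equal(kept$junction, "TGTAAA")
  # order invariance
  kept2 <- dominant_chain_filter(rec[c(3, 1, 2), ])
  expect_equal(kept2, kept)
})

test_that("trajectory classification uses the strict post > pre rule", {
  mk <- function(pid, tp, bcr) {
    tibble::tibble(sample_id = paste0(pid, "_", tp), patient_id = pid,
                   timepoint = tp, bcr_unique = bcr, tcr_unique = 0L,
                   cell_total = bcr)
  }
  up <- classify_trajectory(mk("p1", "pre", 10L), mk("p1", "post", 15L), "BCR")
  expect_equal(up$delta, 5L)
  expect_true(up$increased)

  tie <- classify_trajectory(mk("p2", "pre", 12L), mk("p2", "post", 12L), "BCR")
  expect_equal(tie$delta, 0L)
  expect_false(tie$increased)

  zero <- classify_trajectory(mk("p3", "pre", 0L), mk("p3", "post", 1L), "BCR")
  expect_true(zero$increased)

  expect_error(classify_trajectory(mk("p1", "pre", 1L), mk("p2", "post", 2L),
                                   "BCR"), class = "ct_input_error")
  expect_error(classify_trajectory(mk("p1", "post", 1L), mk("p1", "pre", 2L),
                                   "BCR"), class = "ct_input_error")
})

test_that("vectorized trajectories agree with the pairwise classifier", {
  coh <- generate_cohort(small_config(), include = "repertoire")
  traj <- diversity_trajectories(coh$clonotypes, "BCR")
  reps <- sample_repertoire(coh$clonotypes)
  for (pid in traj$patient_id) {
    pre <- reps[reps$patient_id == pid & reps$timepoint == "pre", ]
    post <- reps[reps$patient_id == pid & reps$timepoint == "post", ]
    one <- classify_trajectory(pre, post, "BCR")
    row <- traj[traj$patient_id == pid, ]
    expect_equal(row$delta, one$delta)
    expect_equal(row$increased, one$increased)
  }
  # swapping arguments flips the sign of delta
  pre <- reps[reps$patient_id == traj$patient_id[1] & reps$timepoint == "pre", ]
  post <- reps[reps$patient_id == traj$patient_id[1] & reps$timepoint == "post", ]
  fwd <- classify_trajectory(pre, post, "BCR")
  swapped <- pre
  swapped$timepoint <- "post"
  post2 <- post
  post2$timepoint <- "pre"
  bwd <- classify_trajectory(post2, swapped, "BCR")
  expect_equal(bwd$delta, -fwd$delta)
})

test_that("static diversity splits strictly above the cohort median", {
  r <- classify_static_diversity(c(s1 = 1, s2 = 2, s3 = 3))
  expect_equal(r$diversity, c("low", "low", "high"))
  r2 <- classify_static_diversity(c(a = 4, b = 4, c = 4))
  expect_true(all(r2$diversity == "low"))
  r3 <- classify_static_diversity(c(a = 0, b = 0, c = 5, d = 10))
  expect_equal(r3$diversity[r3$sample_id %in% c("c", "d")], c("high", "high"))
  expect_equal(r3$diversity[r3$sample_id %in% c("a", "b")], c("low", "low"))
  expect_error(classify_static_diversity(c(a = 1)), class = "ct_input_error")
})

test_that("V-gene usage frequencies are normalized per sample", {
  rec <- toy_clonotypes(loci = rep("IGH", 4), v_calls = rep("IGHV1-2", 4),
                        junctions = paste0("TGTAA", c("A", "C", "G", "T")))
  u <- vgene_usage(rec, "IGH", universe = c("IGHV1-2", "IGHV3-23"))
  expect_equal(u$frequency[u$v_gene == "IGHV1-2"], 1)
  expect_equal(u$frequency[u$v_gene == "IGHV3-23"], 0)

  # empty sample: all-zero vector flagged empty
  u2 <- vgene_usage(dplyr::mutate(rec, locus = "IGK"), "IGH",
                    universe = c("IGHV1-2"))
  expect_true(all(u2$frequency == 0))
  expect_true(all(u2$empty))

  # out-of-universe calls bucketed as "other" with a warning
  expect_warning(
    u3 <- vgene_usage(rec, "IGH", universe = c("IGHV9")),
    "other")
  expect_equal(u3$frequency[u3$v_gene == "other"], 1)
})

test_that("sampled usage approaches the planted spectrum in total variation", {
  p <- withr::with_seed(5, {
    g <- rgamma(25, 0.5)
    g / sum(g)
  })
  genes <- paste0("IGHV", seq_along(p))
  draws <- withr::with_seed(6, sample(genes, 1e4, replace = TRUE, prob = p))
  rec <- toy_clonotypes(loci = rep("IGH", 1e4), v_calls = draws,
                        junctions = paste0("TGT", seq_len(1e4), "TTT"),
                        cell_ids = paste0("c", seq_len(1e4)))
  u <- vgene_usage(rec, "IGH", universe = genes)
  tv <- sum(abs(u$frequency[match(genes, u$v_gene)] - p)) / 2
  expect_lt(tv, 0.05)
})

test_that("usage correlation is symmetric with exact limits at identity and reversal", {
  u1 <- tibble::tibble(v_gene = paste0("IGHV", 1:5),
                       frequency = c(0.4, 0.3, 0.15, 0.1, 0.05))
  expect_equal(usage_correlation(u1, u1)$rho, 1)
  u_rev <- tibble::tibble(v_gene = paste0("IGHV", 1:5),
                          frequency = rev(u1$frequency))
  expect_equal(usage_correlation(u1, u_rev)$rho, -1)
  u2 <- tibble::tibble(v_gene = paste0("IGHV", 1:5),
                       frequency = c(0.1, 0.5, 0.05, 0.2, 0.15))
  expect_equal(usage_correlation(u1, u2)$rho, usage_correlation(u2, u1)$rho)
  tiny <- tibble::tibble(v_gene = c("IGHV1", "IGHV2"), frequency = c(0.5, 0.5))
  expect_error(usage_correlation(tiny, tiny), class = "ct_undefined_error")
})

test_that("matched usage exceeds mismatched usage across modalities", {
  cfg <- cohort_config(n_patients = 3, n_cells_spatial = 900, seed = 31)
  coh <- generate_cohort(cfg, include = c("repertoire", "spatial"),
                         n_spatial_patients = 3)
  maps <- Filter(function(x) x$compartment == "lymph_node" || !x$treated,
                 coh$spatial)
  uv <- usage_validation(coh$clonotypes, maps,
                         universe = paste0("IGHV", seq_len(cfg$n_vgenes)))
  expect_gt(mean(uv$rho[uv$matched]), mean(uv$rho[!uv$matched]))
})
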