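ct_class_loci <- function(receptor_class) {
  switch(receptor_class,
         TCR = c("TRA", "TRB"),
         BCR = c("IGH", "IGK", "IGL"),
         abort("`receptor_class` must be 'TCR' or 'BCR'.",
               class = "ct_input_error"))
}

#' Dominant-chain filter
#'
#' If a cell carries multiple records for the same locus (doublets,
#' ambient chains), keep the record with the highest `duplicate_count`;
#' ties are broken by lexicographically smallest junction, so the filter is
#' deterministic and order-invariant.
#'
#' @param records clonotype record tibble (see [read_airr()]).
#' @return filtered tibble with one record per (sample, cell, locus).
#' @export
dominant_chain_filter <- function(records) {
  records <- validate_clonotypes(records)
  key <- paste(records$sample_id, records$cell_id, records$locus, sep = "\r")
  ord <- order(key, -records$duplicate_count, records$junction,
               method = "radix")
  kept <- records[ord, ][!duplicated(key[ord]), ]
  tibble::as_tibble(kept)
}

#' Count unique clonotypes per sample
#'
#' A clonotype is keyed by (locus, V gene, CDR3 nucleotide junction) after
#' dominant-chain filtering; counts are cell-level (one vote per cell). The
#' BCR class pools IGH/IGK/IGL keys, the TCR class pools TRA/TRB. Samples
#' present in the table but with no records of the class report 0.
#'
#' @param records clonotype record tibble.
#' @param receptor_class `"BCR"` or `"TCR"`.
#' @return tibble with `sample_id`, `receptor_class`, `n_unique`,
#'   `n_cells` (cells of the class after filtering).
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   cell_id = paste0("c", 1:5), sample_id = "s1", locus = "IGH",
#'   v_call = c("IGHV1", "IGHV1", "IGHV2", "IGHV2", "IGHV3"),
#'   junction = c("TGTA", "TGTA", "TGTC", "TGTC", "TGTG"),
#'   duplicate_count = 1L)
#' count_unique_clonotypes(rec, "BCR") # 3 distinct keys
count_unique_clonotypes <- function(records, receptor_class = c("BCR", "TCR")) {
  receptor_class <- match.arg(receptor_class)
  records <- dominant_chain_filter(records)
  ct_count_unique_filtered(records, receptor_class)
}

# counting on records already passed through the dominant-chain filter
ct_count_unique_filtered <- function(records, receptor_class) {
  loci <- ct_class_loci(receptor_class)
  all_samples <- unique(records$sample_id)
  counted <- records |>
    dplyr::filter(.data$locus %in% loci) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_unique = dplyr::n_distinct(paste(.data$locus, .data$v_call,
                                         .data$junction, sep = "|")),
      n_cells = dplyr::n(), .groups = "drop")
  tibble::tibble(sample_id = all_samples) |>
    dplyr::left_join(counted, by = "sample_id") |>
    dplyr::mutate(receptor_class = receptor_class,
                  n_unique = dplyr::coalesce(.data$n_unique, 0L),
                  n_cells = dplyr::coalesce(.data$n_cells, 0L)) |>
    dplyr::select("sample_id", "receptor_class", "n_unique", "n_cells")
}

#' Summarize a sample's repertoire
#'
#' @param records clonotype record tibble (may span samples).
#' @return tibble with one row per sample: `sample_id`, `patient_id`,
#'   `timepoint` (when present in the input), `bcr_unique`, `tcr_unique`,
#'   `cell_total`. Counts are cell-level, flagged in the
#'   `count_level` attribute.
#' @export
sample_repertoire <- function(records) {
  filtered <- dominant_chain_filter(records)
  bcr <- ct_count_unique_filtered(filtered, "BCR")
  tcr <- ct_count_unique_filtered(filtered, "TCR")
  meta_cols <- intersect(c("patient_id", "timepoint"), names(records))
  meta <- records |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("sample_id", meta_cols))))
  totals <- filtered |>
    dplyr::count(.data$sample_id, name = "cell_total")
  out <- meta |>
    dplyr::left_join(dplyr::select(bcr, "sample_id", bcr_unique = "n_unique"),
                     by = "sample_id") |>
    dplyr::left_join(dplyr::select(tcr, "sample_id", tcr_unique = "n_unique"),
                     by = "sample_id") |>
    dplyr::left_join(totals, by = "sample_id")
  attr(out, "count_level") <- "cell"
  out
}

#' Classify a patient's pre/post diversity trajectory
#'
#' Induced diversity means a strictly greater unique clonotype count in the
#' post-treatment sample than in the pre-treatment sample; ties are not an
#' increase.
#'
#' @param pre,post one-row tibbles from [sample_repertoire()] for the same
#'   patient's pre and post samples.
#' @param receptor_class `"BCR"` or `"TCR"`.
#' @return one-row tibble: `patient_id`, `receptor_class`, `pre_count`,
#'   `post_count`, `delta`, `increased`.
#' @export
classify_trajectory <- function(pre, post, receptor_class = c("BCR", "TCR")) {
  receptor_class <- match.arg(receptor_class)
  if (nrow(pre) != 1L || nrow(post) != 1L) {
    abort("`pre` and `post` must be one-row repertoire summaries.",
          class = "ct_input_error")
  }
  if (!identical(pre$patient_id, post$patient_id)) {
    abort("`pre` and `post` belong to different patients.",
          class = "ct_input_error")
  }
  if (!identical(pre$timepoint, "pre") || !identical(post$timepoint, "post")) {
    abort("Timepoints must be pre then post.", class = "ct_input_error")
  }
  col <- if (receptor_class == "BCR") "bcr_unique" else "tcr_unique"
  pre_count <- pre[[col]]
  post_count <- post[[col]]
  tibble::tibble(
    patient_id = pre$patient_id,
    receptor_class = receptor_class,
    pre_count = pre_count,
    post_count = post_count,
    delta = post_count - pre_count,
    increased = post_count > pre_count
  )
}

#' Diversity trajectories for every patient in a clonotype table
#'
#' Convenience wrapper: summarizes repertoires with [sample_repertoire()]
#' and applies [classify_trajectory()] to each patient with both a pre and
#' a post sample.
#'
#' @param records clonotype record tibble with `patient_id` and `timepoint`.
#' @inheritParams classify_trajectory
#' @return tibble of per-patient trajectories.
#' @export
diversity_trajectories <- function(records, receptor_class = c("BCR", "TCR")) {
  receptor_class <- match.arg(receptor_class)
  reps <- sample_repertoire(records)
  if (!all(c("patient_id", "timepoint") %in% names(reps))) {
    abort("Records need `patient_id` and `timepoint` for trajectories.",
          class = "ct_input_error")
  }
  col <- if (receptor_class == "BCR") "bcr_unique" else "tcr_unique"
  wide <- reps |>
    dplyr::filter(.data$timepoint %in% c("pre", "post")) |>
    dplyr::select("patient_id", "timepoint", count = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "count",
                       values_fn = list) |>
    dplyr::filter(lengths(.data$pre) == 1L, lengths(.data$post) == 1L) |>
    dplyr::mutate(pre = unlist(.data$pre), post = unlist(.data$post))
  # vectorized form of classify_trajectory(): strict post > pre rule
  tibble::tibble(
    patient_id = wide$patient_id,
    receptor_class = receptor_class,
    pre_count = wide$pre,
    post_count = wide$post,
    delta = wide$post - wide$pre,
    increased = wide$post > wide$pre
  )
}

#' Static above-median diversity classification
#'
#' A sample is "high" when its count strictly exceeds the cohort median of
#' the supplied counts.
#'
#' @param counts tibble with `sample_id` and `n_unique` (as from
#'   [count_unique_clonotypes()]), or a named numeric vector.
#' @return tibble with `sample_id`, `n_unique`, `diversity` (`"high"` /
#'   `"low"`).
#' @export
classify_static_diversity <- function(counts) {
  if (is.numeric(counts)) {
    counts <- tibble::tibble(sample_id = names(counts) %||%
                               as.character(seq_along(counts)),
                             n_unique = unname(counts))
  }
  if (nrow(counts) < 2L) {
    abort("Static diversity needs at least 2 samples.",
          class = "ct_input_error")
  }
  med <- median(counts$n_unique)
  counts |>
    dplyr::mutate(diversity = ifelse(.data$n_unique > med, "high", "low"))
}

#' V-gene usage frequencies per sample
#'
#' One vote per cell after dominant-chain filtering. V calls outside the
#' supplied universe are bucketed as `"other"` with a warning; the bucket
#' is excluded from correlation support downstream.
#'
#' @param records clonotype record tibble.
#' @param locus a single locus (`"IGH"`, `"TRA"`, ...).
#' @param universe character vector of V genes defining the frequency
#'   vector; defaults to the sorted genes observed at that locus.
#' @return tibble with `sample_id`, `v_gene`, `frequency`; frequencies sum
#'   to 1 per sample with any record, and are all zero (with an `empty`
#'   flag column) otherwise.
#' @export
vgene_usage <- function(records, locus, universe = NULL) {
  if (!locus %in% c("TRA", "TRB", "IGH", "IGK", "IGL")) {
    abort("Invalid `locus`.", class = "ct_input_error")
  }
  records <- dominant_chain_filter(records)
  all_samples <- unique(records$sample_id)
  rec <- dplyr::filter(records, .data$locus == .env$locus)
  if (is.null(universe)) universe <- sort(unique(rec$v_call))
  out_of <- setdiff(unique(rec$v_call), universe)
  if (length(out_of)) {
    warn(paste0(length(out_of), " V call(s) outside the universe bucketed",
                " as 'other'."))
    rec$v_call[rec$v_call %in% out_of] <- "other"
    universe <- c(universe, "other")
  }
  grid <- tidyr::expand_grid(sample_id = all_samples, v_gene = universe)
  tallies <- rec |>
    dplyr::count(.data$sample_id, v_gene = .data$v_call, name = "n")
  grid |>
    dplyr::left_join(tallies, by = c("sample_id", "v_gene")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$n),
                  frequency = ifelse(.data$total > 0, .data$n / .data$total, 0),
                  empty = .data$total == 0) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "v_gene", "frequency", "empty")
}

#' Spearman correlation between two V-gene usage vectors
#'
#' Computed over the union support: V genes with nonzero frequency in at
#' least one of the two vectors, excluding any `"other"` bucket. Requires
#' support of at least 3 genes.
#'
#' @param a,b usage tibbles for a single sample each (columns `v_gene`,
#'   `frequency`), as returned by [vgene_usage()] or
#'   [pseudoclone_usage()].
#' @param matched optional logical tag (same patient and timepoint) carried
#'   into the output.
#' @return one-row tibble: `rho`, `n_support`, `matched`.
#' @export
usage_correlation <- function(a, b, matched = NA) {
  joined <- dplyr::full_join(
    dplyr::select(a, "v_gene", freq_a = "frequency"),
    dplyr::select(b, "v_gene", freq_b = "frequency"),
    by = "v_gene") |>
    dplyr::mutate(freq_a = dplyr::coalesce(.data$freq_a, 0),
                  freq_b = dplyr::coalesce(.data$freq_b, 0)) |>
    dplyr::filter(.data$v_gene != "other",
                  .data$freq_a > 0 | .data$freq_b > 0)
  if (nrow(joined) < 3L) {
    abort("Usage correlation undefined: union support below 3 genes.",
          class = "ct_undefined_error")
  }
  rho <- suppressWarnings(
    cor(joined$freq_a, joined$freq_b, method = "spearman"))
  tibble::tibble(rho = rho, n_support = nrow(joined), matched = matched)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Matched vs mismatched V-gene usage validation
#'
#' Pairs every spatial map with every scRNA repertoire sample and computes
#' the IGH usage correlation ([usage_correlation()]), tagging pairs from
#' the same patient and clinical timepoint as matched (a treated map is a
#' post-treatment timepoint, an untreated map pre-treatment). Matched pairs
#' share a usage spectrum, mismatched pairs should not — the validation
#' that V-gene usage tracks clonotype composition across modalities.
#'
#' @param clonotypes clonotype record tibble (with `patient_id`,
#'   `timepoint`).
#' @param spatial_samples list of `ct_spatial_sample` maps.
#' @param universe V-gene universe for the frequency vectors (default: the
#'   IGH genes observed in the repertoire).
#' @return tibble with `map`, `sample_id`, `matched`, `rho`, `n_support`.
#' @export
usage_validation <- function(clonotypes, spatial_samples, universe = NULL) {
  u_sc <- vgene_usage(clonotypes, "IGH", universe = universe)
  rows <- list()
  for (sp in spatial_samples) {
    a <- suppressWarnings(assign_pseudoclones(sp$cells, "IGH"))
    if (nrow(a) == 0) next
    u_sp <- pseudoclone_usage(a, universe = universe)
    tp <- if (isTRUE(sp$treated)) "post" else "pre"
    for (sid in unique(u_sc$sample_id)) {
      one <- dplyr::filter(u_sc, .data$sample_id == sid)
      matched <- identical(sid, paste0(sp$patient_id, "_", tp))
      cc <- tryCatch(usage_correlation(one, u_sp, matched = matched),
                     ct_undefined_error = function(e) NULL)
      if (is.null(cc)) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(map = sp$sample_id, sample_id = sid), cc)
    }
  }
  dplyr::bind_rows(rows)
}
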