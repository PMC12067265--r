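# Small configurations and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (quadratic/cubic loops, direct
# tabulation, grid search) and never share code with the implementation.

small_config <- function(...) {
  defaults <- list(n_patients = 4, n_genes = 40, n_cells_per_sample = 60,
                   n_cells_spatial = 400, n_vgenes = 20, seed = 42)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

toy_clonotypes <- function(sample_id = "s1", loci, v_calls, junctions,
                           cell_ids = NULL, dup = NULL) {
  n <- length(loci)
  tibble::tibble(
    cell_id = cell_ids %||% paste0("c", seq_len(n)),
    sample_id = sample_id,
    locus = loci,
    v_call = v_calls,
    junction = junctions,
    junction_aa = substr(junctions, 1, 3),
    duplicate_count = dup %||% rep(1L, n)
  )
}

random_map <- function(n, field = 300, types = c("A", "B", "C"),
                       probs = NULL, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = paste0("cell", seq_len(n)),
    x_um = runif(n, 0, field),
    y_um = runif(n, 0, field),
    cell_type = sample(types, n, replace = TRUE, prob = probs)
  ))
}

# O(n^2) proximity oracle: every pair, direct distance
oracle_proximity <- function(cells, radius) {
  n <- nrow(cells)
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                (cells$y_um[i] - cells$y_um[j])^2)
      if (d <= radius) {
        out[[length(out) + 1]] <- c(i = i, j = j, d = d)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(cell_a = character(), cell_b = character(),
                          distance_um = numeric()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(cell_a = cells$cell_id[m[, "i"]],
                 cell_b = cells$cell_id[m[, "j"]],
                 distance_um = m[, "d"])
}

# O(n^3) triad oracle: enumerate A-B pairs, then scan all C cells
oracle_triad <- function(cells, a, b, c, radius, mode = "either") {
  n <- nrow(cells)
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  ia <- which(cells$cell_type == a)
  ib <- which(cells$cell_type == b)
  ic <- which(cells$cell_type == c)
  pairs <- list()
  for (i in ia) {
    for (j in ib) {
      if (i == j) next
      key <- paste(sort(c(i, j)), collapse = "-")
      if (d[i, j] <= radius) pairs[[key]] <- c(i, j)
    }
  }
  n_pairs <- length(pairs)
  if (n_pairs == 0) return(list(n_pairs = 0L, n_with_c = 0L, prob = NA_real_))
  hits <- 0L
  for (p in pairs) {
    near_i <- any(ic != p[1] & d[p[1], ic] <= radius)
    near_j <- any(ic != p[2] & d[p[2], ic] <= radius)
    ok <- if (mode == "either") near_i || near_j else near_i && near_j
    if (ok) hits <- hits + 1L
  }
  list(n_pairs = n_pairs, n_with_c = hits, prob = hits / n_pairs)
}

# hand product-limit estimator (single group)
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  tibble::tibble(time = ts, survival = out)
}

# two-group log-rank by direct hypergeometric tabulation
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tk in ts) {
    n_total <- sum(time >= tk)
    n1 <- sum(time >= tk & group == g1)
    d_total <- sum(time == tk & event == 1)
    d1 <- sum(time == tk & event == 1 & group == g1)
    e1 <- d_total * n1 / n_total
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_total > 1) {
      v <- v + d_total * (n1 / n_total) * (1 - n1 / n_total) *
        (n_total - d_total) / (n_total - 1)
    }
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p_value = pchisq(chi, 1, lower.tail = FALSE))
}

# Breslow log partial likelihood for a binary covariate at log-HR beta
oracle_cox_loglik <- function(time, event, x, beta) {
  ll <- 0
  for (tk in sort(unique(time[event == 1]))) {
    dead <- which(time == tk & event == 1)
    risk <- which(time >= tk)
    ll <- ll + sum(beta * x[dead]) -
      length(dead) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# grid-search maximizer of the Breslow partial likelihood
oracle_cox_grid <- function(time, event, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(b) oracle_cox_loglik(time, event, x, b),
               numeric(1))
  grid[which.max(ll)]
}

# streaming Pearson correlation (one pass, running sums)
oracle_streaming_pearson <- function(x, y) {
  n <- 0; sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (k in seq_along(x)) {
    n <- n + 1
    sx <- sx + x[k]; sy <- sy + y[k]
    sxx <- sxx + x[k]^2; syy <- syy + y[k]^2; sxy <- sxy + x[k] * y[k]
  }
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
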