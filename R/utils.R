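#' Derive a child seed from a parent seed and a key
#'
#' The synthetic cohort generator draws every patient, sample, and map from
#' its own child seed, derived deterministically from the cohort seed.
#' Subsetting patients therefore never changes another patient's draws.
#' Keys may be integers or strings; strings are folded to an integer first.
#' All seeds stay inside the 32-bit integer range.
#'
#' @param seed parent seed (integer).
#' @param key integer or character key identifying the child stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
mix_seed <- function(seed, key) {
  if (is.character(key)) {
    key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  }
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  k <- (as.numeric(key) %% m)
  # two rounds of a Lehmer-style mix keep low-order keys well separated
  s <- (s * 48271 + k * 16807 + 12345) %% m
  s <- (s * 69621 + 30307) %% m
  as.integer(s + 1)
}

#' Evaluate code with a temporary RNG seed
#'
#' Equivalent to `withr::with_seed` for the default RNG, but cheap enough
#' for the generator's per-sample seed tree (thousands of calls per
#' cohort).
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Library-size normalization followed by log1p
#'
#' Scales each cell's counts to a common library size, then applies
#' `log1p`. This is the normalization used for all pseudobulk and
#' differential-expression computations in the package.
#'
#' @param counts cell-by-gene numeric matrix of raw counts.
#' @param scale_to target library size (default 1e4).
#' @return matrix of the same shape, normalized and log1p-transformed.
#'   Cells with zero total count are left at zero.
#' @export
normalize_log1p <- function(counts, scale_to = 1e4) {
  stopifnot(is.matrix(counts) || inherits(counts, "Matrix"))
  lib <- Matrix::rowSums(counts)
  lib[lib == 0] <- 1
  log1p(counts * (scale_to / lib))
}

assert_flag <- function(x, name) {
  if (!(is.logical(x) && length(x) == 1L && !is.na(x))) {
    abort(paste0("`", name, "` must be TRUE or FALSE."), class = "ct_input_error")
  }
  x
}

assert_count <- function(x, name, min = 1) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
        x == floor(x))) {
    abort(paste0("`", name, "` must be an integer >= ", min, "."),
          class = "ct_config_error")
  }
  as.integer(x)
}

assert_positive <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0)) {
    abort(paste0("`", name, "` must be a strictly positive number."),
          class = "ct_config_error")
  }
  as.numeric(x)
}

assert_fraction <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1)) {
    abort(paste0("`", name, "` must lie in [0, 1]."), class = "ct_config_error")
  }
  as.numeric(x)
}

#' Random CDR3 nucleotide junctions
#'
#' Vectorized generation of in-frame CDR3 nucleotide strings with the
#' canonical TGT...TTT (Cys...Phe) framing, plus their translations.
#'
#' @keywords internal
#' @noRd
random_junctions <- function(n, min_codons = 8, max_codons = 20) {
  if (n == 0L) {
    return(list(junction = character(), junction_aa = character()))
  }
  codon_tab <- c(
    GCT = "A", TGC = "C", GAT = "D", GAA = "E", TTC = "F", GGA = "G",
    CAT = "H", ATC = "I", AAA = "K", CTG = "L", ATG = "M", AAC = "N",
    CCT = "P", CAG = "Q", AGA = "R", AGC = "S", ACC = "T", GTG = "V",
    TGG = "W", TAC = "Y"
  )
  n_mid <- sample(max(min_codons - 2, 1):max(max_codons - 2, 2), n,
                  replace = TRUE)
  maxm <- max(n_mid)
  idx <- matrix(sample.int(length(codon_tab), n * maxm, replace = TRUE),
                nrow = n)
  pad <- col(idx) > n_mid
  nt <- matrix(names(codon_tab)[idx], nrow = n)
  aa <- matrix(unname(codon_tab)[idx], nrow = n)
  nt[pad] <- ""
  aa[pad] <- ""
  list(
    junction = paste0("TGT", do.call(paste0, asplit(nt, 2)), "TTT"),
    junction_aa = paste0("C", do.call(paste0, asplit(aa, 2)), "F")
  )
}
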