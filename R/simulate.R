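AGGREGATION_PRONE <- c("V", "I", "F", "Y", "L", "T")
AGGREGATION_BREAKING <- c("P", "G", "D", "E", "K", "R")

profile_from <- function(residues) {
  p <- stats::setNames(rep(0, 20), AA_ALPHABET)
  p[residues] <- 1 / length(residues)
  p
}

#' Generate a labeled synthetic hexmer dataset
#'
#' Draws positive windows i.i.d. per position from an aggregation-prone
#' residue profile (enriched in V, I, F, Y, L, T, following the
#' beta-sheet-prone enrichment reported for amyloid-forming segments) and
#' negative windows from an aggregation-breaking profile (P, G, D, E, K,
#' R). `effect` interpolates both profiles toward the uniform distribution:
#' at `effect = 0` the classes are generated by the same law, at
#' `effect = 1` their residue supports are disjoint. Default sample sizes
#' mirror the scale of the curated hexmer benchmark the architecture was
#' built for (1232 positive / 1280 negative).
#'
#' @param n_pos,n_neg Number of positive / negative hexmers.
#' @param effect Separation strength in `[0, 1]`.
#' @param positive_profile,negative_profile Optional named probability
#'   vectors over the 20 residues replacing the defaults.
#' @param window Window width (default 6).
#' @param seed Seed; the generator is a pure function of its arguments.
#' @return Tibble with columns `sequence` and `label` (1 = positive).
#' @examples
#' synthesize_hexmers(n_pos = 3, n_neg = 3, effect = 1, seed = 1)
#' @export
synthesize_hexmers <- function(n_pos = 1232L, n_neg = 1280L, effect = 1,
                               positive_profile = NULL,
                               negative_profile = NULL,
                               window = 6L, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, effect >= 0, effect <= 1)
  pos_base <- positive_profile %||% profile_from(AGGREGATION_PRONE)
  neg_base <- negative_profile %||% profile_from(AGGREGATION_BREAKING)
  for (p in list(pos_base, neg_base)) {
    if (!setequal(names(p), AA_ALPHABET) || abs(sum(p) - 1) > 1e-8 ||
        any(p < 0)) {
      abort("Profiles must be probability vectors over the 20 residues.")
    }
  }
  uniform <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  pos_p <- effect * pos_base[AA_ALPHABET] + (1 - effect) * uniform
  neg_p <- effect * neg_base[AA_ALPHABET] + (1 - effect) * uniform

  draw <- function(n, p) {
    chars <- sample(AA_ALPHABET, n * window, replace = TRUE, prob = p)
    apply(matrix(chars, nrow = n), 1, paste, collapse = "")
  }
  with_seed(seed, {
    tibble(
      sequence = c(draw(n_pos, pos_p), draw(n_neg, neg_p)),
      label = rep(c(1L, 0L), c(n_pos, n_neg)))
  })
}

#' Generate synthetic amino-acid property indices
#'
#' Each index assigns an independent standard-normal value to every
#' residue; indices whose population standard deviation over the 20
#' residues falls below 0.2 are redrawn, so no near-constant index is ever
#' produced. Accessions are `SYN0001`, `SYN0002`, ... These stand in for a
#' real property database in tests and simulations.
#'
#' @param n Number of indices.
#' @param seed Seed.
#' @return Index tibble as returned by [read_aaindex()].
#' @export
synthesize_indices <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  values <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      repeat {
        v <- rnorm(20)
        if (sqrt(mean((v - mean(v))^2)) >= 0.2) return(v)
      }
    }, numeric(20)))
  })
  colnames(values) <- AA_ALPHABET
  aaindex_tibble(
    accession = sprintf("SYN%04d", seq_len(n)),
    description = sprintf("Synthetic amino-acid index %d", seq_len(n)),
    values = values)
}

#' Generate a planted-signal feature matrix
#'
#' A test harness for the feature-selection engine: `pool_size` feature
#' columns of Gaussian noise, of which `n_planted` carry a between-class
#' mean shift (`+shift/2` for positives, `-shift/2` for negatives). All
#' other columns are independent of the class.
#'
#' @param pool_size Number of feature columns.
#' @param n_planted Number of informative columns.
#' @param shift Class mean separation of planted columns in noise standard
#'   deviations. The default of 1 makes each planted feature weakly
#'   informative on its own (single-feature Bayes accuracy about 0.69)
#'   while the joint signal of 10 planted features is strong (Mahalanobis
#'   distance `sqrt(10)`, Bayes accuracy about 0.94) - the regime
#'   wrapper-based subset selection is designed for. Larger shifts (e.g. 3)
#'   make single features individually decisive.
#' @param noise_sd Noise standard deviation (default 1).
#' @param n_per_class Samples per class.
#' @param seed Seed.
#' @return List with `data` (tibble: `label` plus feature columns
#'   `PROP001`, ...) and `design` (list: `pool`, `planted`, `shift`,
#'   `noise_sd`, `seed`).
#' @examples
#' sim <- synthesize_planted(pool_size = 8, n_planted = 2,
#'                           n_per_class = 10, seed = 1)
#' sim$design$planted
#' @export
synthesize_planted <- function(pool_size = 186L, n_planted = 10L,
                               shift = 1, noise_sd = 1,
                               n_per_class = 100L, seed = 1L) {
  stopifnot(n_planted <= pool_size, n_planted >= 0L, noise_sd > 0,
            n_per_class >= 2L)
  pool <- sprintf("PROP%03d", seq_len(pool_size))
  with_seed(seed, {
    planted <- sort(sample(pool, n_planted))
    n <- 2L * n_per_class
    label <- rep(c(1L, 0L), each = n_per_class)
    mat <- matrix(rnorm(n * pool_size, sd = noise_sd), n, pool_size,
                  dimnames = list(NULL, pool))
    for (f in planted) {
      mat[, f] <- mat[, f] + ifelse(label == 1L, shift / 2, -shift / 2)
    }
    list(data = bind_cols(tibble(label = label),
                          as_tibble(as.data.frame(mat))),
         design = list(pool = pool, planted = planted, shift = shift,
                       noise_sd = noise_sd, seed = seed))
  })
}
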