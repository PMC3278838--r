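#' Moreau-Broto autocorrelation of per-position property values
#'
#' For a window of `w` per-position property values `p`, the lag-`v`
#' autocorrelation is
#' \deqn{F_v = \frac{1}{w - v} \sum_{i=1}^{w-v} p_i \, p_{i+v}}
#' i.e. the average product of property values at positions `v` apart. It is
#' the sequence-order-sensitive companion to the order-free per-window mean:
#' shuffling a window generally changes \eqn{F_v} while leaving the mean and
#' the atomic composition untouched. `lag_normalized = FALSE` gives the
#' plain unnormalized sum \eqn{\sum p_i p_{i+v}}.
#'
#' @param p Numeric vector of per-position property values (length `w`).
#' @param lag Lag `v`, an integer in `1 .. w - 1`.
#' @param lag_normalized Divide the sum by the number of terms `w - v`
#'   (default) or return the raw sum.
#' @return A single number.
#' @examples
#' moreau_broto(1:6, lag = 1) # (1*2 + 2*3 + 3*4 + 4*5 + 5*6) / 5 = 14
#' @export
moreau_broto <- function(p, lag, lag_normalized = TRUE) {
  w <- length(p)
  lag <- as.integer(lag)
  if (lag < 1L || lag >= w) {
    abort(sprintf("`lag` must be in 1 .. %d for a window of width %d.",
                  w - 1L, w))
  }
  s <- sum(p[seq_len(w - lag)] * p[(lag + 1L):w])
  if (lag_normalized) s / (w - lag) else s
}

#' Atomic composition of peptide windows
#'
#' Sums the C/H/N/O/S atom counts of the constituent residues (dehydrated,
#' in-chain formulas; see [atomic_table()]). Composition is invariant under
#' any permutation of the window.
#'
#' @param hexmers Character vector of peptide windows over the standard
#'   20-letter alphabet.
#' @return Tibble with integer columns `C`, `H`, `N`, `O`, `S`, one row per
#'   window.
#' @examples
#' atomic_composition("AAAAAA") # C 18, H 30, N 6, O 6, S 0
#' @export
atomic_composition <- function(hexmers) {
  tab <- atomic_table()
  chars <- strsplit(toupper(hexmers), "")
  bad <- map_chr(chars, function(cc) {
    miss <- setdiff(cc, tab$residue)
    if (length(miss)) miss[1L] else NA_character_
  })
  if (any(!is.na(bad))) {
    abort(sprintf("Non-standard residue '%s' in window '%s'.",
                  bad[which(!is.na(bad))[1L]],
                  hexmers[which(!is.na(bad))[1L]]))
  }
  counts <- map(chars, function(cc) {
    idx <- match(cc, tab$residue)
    colSums(tab[idx, c("C", "H", "N", "O", "S")])
  })
  out <- as_tibble(do.call(rbind, counts))
  mutate(out, across(dplyr::everything(), as.integer))
}

#' Feature-encoding configuration
#'
#' Describes which of the three feature blocks to compute and from which
#' amino-acid indices:
#' * `BPC` - one feature per property: the arithmetic mean of the raw index
#'   values over the window's residues (order-free);
#' * `AC` - Moreau-Broto autocorrelation [moreau_broto()] of each `ac`
#'   property at lags `1 .. max_lag`, computed on standardized index values
#'   (order-sensitive);
#' * `ATOM` - the five C/H/N/O/S atom counts.
#'
#' @param bpc Character vector of index accessions for the BPC block.
#' @param ac Character vector of accessions for the autocorrelation block
#'   (canonically the best 5 properties from pre-selection).
#' @param blocks Which blocks to include; non-empty subset of
#'   `c("BPC", "AC", "ATOM")`.
#' @param max_lag Largest autocorrelation lag; must be smaller than the
#'   window width (default 5 for hexmers, giving lags 1-5).
#' @param window Window width the encoding expects (default 6).
#' @param lag_normalized Passed to [moreau_broto()].
#' @param standardize_ac Standardize indices (mean 0, sd 1 over residues)
#'   before autocorrelation (default TRUE).
#' @return An `encoding_config` object.
#' @seealso [encode_hexmers()], [pm_config()]
#' @export
encoding_config <- function(bpc = character(), ac = character(),
                            blocks = c("BPC", "AC", "ATOM"),
                            max_lag = 5L, window = 6L,
                            lag_normalized = TRUE, standardize_ac = TRUE) {
  blocks <- match.arg(blocks, several.ok = TRUE)
  if (length(blocks) == 0L) abort("`blocks` must be non-empty.")
  max_lag <- as.integer(max_lag)
  window <- as.integer(window)
  if (max_lag >= window || max_lag < 1L) {
    abort("`max_lag` must be in 1 .. window - 1.")
  }
  if ("BPC" %in% blocks && length(bpc) == 0L) {
    abort("BPC block requested but `bpc` accession list is empty.")
  }
  if ("AC" %in% blocks && length(ac) == 0L) {
    abort("AC block requested but `ac` accession list is empty.")
  }
  structure(
    list(bpc = as.character(bpc), ac = as.character(ac),
         blocks = blocks, max_lag = max_lag, window = window,
         lag_normalized = lag_normalized, standardize_ac = standardize_ac),
    class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat("<encoding_config> blocks:", paste(x$blocks, collapse = "+"),
      sprintf("| %d BPC, %d AC x lags 1-%d | %d columns\n",
              length(x$bpc), length(x$ac), x$max_lag, n_features(x)))
  invisible(x)
}

# Declared column count of a config (BPC + AC*max_lag + 5*ATOM).
n_features <- function(config) {
  sum(c(BPC = length(config$bpc),
        AC = length(config$ac) * config$max_lag,
        ATOM = 5L)[config$blocks])
}

#' Encode hexmer windows as a feature matrix
#'
#' Assembles the configured feature blocks in the fixed order BPC, AC, ATOM.
#' BPC columns are named by accession, AC columns `accession:lag`, and ATOM
#' columns `ATOM_C` .. `ATOM_S`. Under the five canonical prediction-model
#' configurations the column counts are 40 (PM1), 5 (PM2), 65 (PM3), 45
#' (PM4) and 70 (PM5).
#'
#' @param hexmers Tibble with a `sequence` column (and optional `label`), or
#'   a character vector of windows.
#' @param indices Index tibble covering every accession the config names.
#' @param config An [encoding_config()].
#' @return Tibble with columns `sequence`, `label` (if present in the
#'   input), then one numeric column per feature. The block of each feature
#'   is recorded in the `"feature_info"` attribute (see [feature_info()]);
#'   values are raw (un-normalized).
#' @examples
#' idx <- synthesize_indices(6, seed = 1)
#' cfg <- encoding_config(bpc = idx$accession, ac = idx$accession[1:2],
#'                        blocks = c("BPC", "AC"))
#' encode_hexmers(c("MKVIFL", "GGGGGG"), idx, cfg)
#' @export
encode_hexmers <- function(hexmers, indices, config) {
  if (is.character(hexmers)) hexmers <- tibble(sequence = hexmers)
  stopifnot(is.data.frame(hexmers), "sequence" %in% names(hexmers))
  check_aaindex(indices)
  stopifnot(inherits(config, "encoding_config"))

  seqs <- toupper(hexmers$sequence)
  if (any(nchar(seqs) != config$window)) {
    abort(sprintf("All windows must have width %d.", config$window))
  }
  need <- unique(c(if ("BPC" %in% config$blocks) config$bpc,
                   if ("AC" %in% config$blocks) config$ac))
  missing_acc <- setdiff(need, indices$accession)
  if (length(missing_acc)) {
    abort(sprintf("Accessions not found in index collection: %s",
                  paste(missing_acc, collapse = ", ")))
  }

  # n x w matrix of residue positions in the alphabet
  chars <- matrix(unlist(strsplit(seqs, "")), ncol = config$window,
                  byrow = TRUE)
  pos <- match(chars, AA_ALPHABET)
  if (anyNA(pos)) {
    bad <- chars[is.na(pos)][1L]
    abort(sprintf("Non-standard residue '%s' in input windows.", bad))
  }
  pos <- matrix(pos, ncol = config$window)

  blocks <- list()
  if ("BPC" %in% config$blocks) {
    vals <- as.matrix(indices[match(config$bpc, indices$accession),
                              AA_ALPHABET])
    bpc <- vapply(seq_along(config$bpc), function(j) {
      rowMeans(matrix(vals[j, ][pos], ncol = config$window))
    }, numeric(nrow(pos)))
    bpc <- matrix(bpc, nrow = nrow(pos),
                  dimnames = list(NULL, config$bpc))
    blocks$BPC <- bpc
  }
  if ("AC" %in% config$blocks) {
    idx_ac <- indices[match(config$ac, indices$accession), , drop = FALSE]
    if (config$standardize_ac) idx_ac <- standardize_indices(idx_ac)
    vals <- as.matrix(idx_ac[, AA_ALPHABET])
    cols <- list()
    for (j in seq_along(config$ac)) {
      p <- matrix(vals[j, ][pos], ncol = config$window)
      for (v in seq_len(config$max_lag)) {
        i <- seq_len(config$window - v)
        s <- rowSums(p[, i, drop = FALSE] * p[, i + v, drop = FALSE])
        if (config$lag_normalized) s <- s / (config$window - v)
        cols[[paste0(config$ac[j], ":", v)]] <- s
      }
    }
    blocks$AC <- do.call(cbind, cols)
  }
  if ("ATOM" %in% config$blocks) {
    atom <- as.matrix(atomic_composition(seqs))
    colnames(atom) <- paste0("ATOM_", c("C", "H", "N", "O", "S"))
    blocks$ATOM <- atom
  }

  block_order <- intersect(c("BPC", "AC", "ATOM"), names(blocks))
  feat <- do.call(cbind, blocks[block_order])
  info <- tibble(
    feature = colnames(feat),
    block = rep(block_order, times = map_int(blocks[block_order], ncol)))

  id_cols <- hexmers[, intersect(c("sequence", "label"), names(hexmers)),
                     drop = FALSE]
  out <- bind_cols(as_tibble(id_cols), as_tibble(as.data.frame(feat)))
  attr(out, "feature_info") <- info
  attr(out, "normalization") <- NULL
  out
}

#' Feature-block bookkeeping of an encoded matrix
#'
#' @param encoded A tibble produced by [encode_hexmers()].
#' @return Tibble with columns `feature` and `block`.
#' @export
feature_info <- function(encoded) {
  attr(encoded, "feature_info") %||%
    tibble(feature = feature_columns(encoded), block = NA_character_)
}

# Names of the numeric feature columns (everything except bookkeeping).
feature_columns <- function(data) {
  setdiff(names(data), c("sequence", "label", "seq_id", "start"))
}
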