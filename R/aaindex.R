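#' Read amino-acid property indices from an AAindex flat file
#'
#' Parses records in the AAindex flat-file dialect: `H` gives the accession,
#' `D` the description, and `I` introduces the 20 per-residue values as two
#' rows of ten numbers in the canonical A R N D C Q E G H I / L K M F P S T W
#' Y V order; `//` terminates a record. All other record lines (`R`, `A`,
#' `T`, `J`, `C`, ...) are ignored. Records whose `I` block contains a
#' missing-value marker (`NA` or `-`) are skipped and reported, mirroring the
#' curation step that drops indices with partial data.
#'
#' @param file Path to a flat file, or a character vector of lines via
#'   [parse_aaindex()].
#' @return A tibble with one row per complete record: columns `accession`,
#'   `description`, and one numeric column per residue (the 20 standard
#'   one-letter codes, alphabetical). Skipped records are attached as a
#'   tibble in the `"skipped"` attribute (see [aaindex_skipped()]) and
#'   reported as messages.
#' @examples
#' fixture <- system.file("extdata", "aaindex_demo.txt", package = "amyhex")
#' idx <- read_aaindex(fixture)
#' idx$accession
#' @seealso [write_aaindex()], [standardize_indices()], [synthesize_indices()]
#' @export
read_aaindex <- function(file) {
  parse_aaindex(readLines(file, warn = FALSE))
}

#' @rdname read_aaindex
#' @param lines Character vector of flat-file lines.
#' @export
parse_aaindex <- function(lines) {
  empty <- aaindex_tibble(character(), character(),
                          matrix(numeric(), ncol = 20L,
                                 dimnames = list(NULL, AA_ALPHABET)))
  attr(empty, "skipped") <- tibble(accession = character(), reason = character())
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    return(empty)
  }

  ends <- which(grepl("^//", lines))
  if (length(ends) == 0L) {
    abort("Malformed AAindex stream: no record terminator ('//') found.")
  }
  starts <- c(1L, head(ends, -1L) + 1L)

  rows <- list()
  skipped <- list()
  for (k in seq_along(ends)) {
    span <- starts[k]:ends[k]
    rec <- lines[span]
    if (all(!nzchar(trimws(rec[rec != "//"])))) next
    parsed <- parse_aaindex_record(rec, first_line = starts[k])
    if (is.null(parsed$values)) {
      inform(sprintf("Skipping AAindex record %s: %s",
                     parsed$accession, parsed$reason))
      skipped[[length(skipped) + 1L]] <-
        tibble(accession = parsed$accession, reason = parsed$reason)
    } else {
      rows[[length(rows) + 1L]] <- parsed
    }
  }

  out <- if (length(rows)) {
    aaindex_tibble(
      accession = map_chr(rows, "accession"),
      description = map_chr(rows, "description"),
      values = do.call(rbind, map(rows, "values"))
    )
  } else {
    empty
  }
  attr(out, "skipped") <- if (length(skipped)) bind_rows(skipped) else
    tibble(accession = character(), reason = character())
  out
}

# One record's lines -> list(accession, description, values | NULL, reason).
parse_aaindex_record <- function(rec, first_line) {
  tags <- substr(rec, 1L, 1L)
  h <- which(tags == "H")
  if (length(h) == 0L) {
    abort(sprintf(
      "Malformed AAindex record starting at line %d: no 'H' (accession) line.",
      first_line))
  }
  accession <- trimws(sub("^H", "", rec[h[1L]]))
  if (!nzchar(accession)) {
    abort(sprintf("Malformed AAindex record at line %d: empty accession.",
                  first_line + h[1L] - 1L))
  }

  d <- which(tags == "D")
  description <- if (length(d)) {
    d_end <- d[1L]
    while (d_end < length(rec) && tags[d_end + 1L] == " " &&
           nzchar(trimws(rec[d_end + 1L]))) {
      d_end <- d_end + 1L
    }
    trimws(paste(trimws(sub("^D", "", rec[d[1L]:d_end])), collapse = " "))
  } else {
    ""
  }

  i <- which(tags == "I")
  if (length(i) == 0L) {
    abort(sprintf("Malformed AAindex record '%s': no 'I' (values) block.",
                  accession))
  }
  val_end <- i[1L]
  while (val_end < length(rec) &&
         grepl("^\\s", rec[val_end + 1L]) && nzchar(trimws(rec[val_end + 1L]))) {
    val_end <- val_end + 1L
  }
  if (val_end == i[1L]) {
    abort(sprintf("Malformed AAindex record '%s': 'I' line has no value rows.",
                  accession))
  }
  tokens <- unlist(strsplit(trimws(rec[(i[1L] + 1L):val_end]), "\\s+"))
  if (length(tokens) != 20L) {
    abort(sprintf(
      "Malformed AAindex record '%s' (line %d): expected 20 values, found %d.",
      accession, first_line + i[1L] - 1L, length(tokens)))
  }
  if (any(tokens %in% c("NA", "-", "NA.", "-."))) {
    return(list(accession = accession, description = description,
                values = NULL, reason = "missing values in 'I' block"))
  }
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals)) {
    abort(sprintf("Malformed AAindex record '%s': non-numeric value '%s'.",
                  accession, tokens[which(is.na(vals))[1L]]))
  }
  named <- stats::setNames(vals, c(AAINDEX_ROW1, AAINDEX_ROW2))
  list(accession = accession, description = description,
       values = named[AA_ALPHABET], reason = NA_character_)
}

aaindex_tibble <- function(accession, description, values) {
  vals <- as_tibble(as.data.frame(values))
  names(vals) <- AA_ALPHABET
  out <- bind_cols(tibble(accession = accession, description = description),
                   vals)
  class(out) <- c("aaindex_tbl", class(out))
  out
}

#' @rdname read_aaindex
#' @param indices An index tibble as returned by [read_aaindex()].
#' @export
aaindex_skipped <- function(indices) {
  attr(indices, "skipped") %||%
    tibble(accession = character(), reason = character())
}

#' Write amino-acid indices back to AAindex flat-file format
#'
#' The inverse of [read_aaindex()]: values are written at full double
#' precision so that a write/re-parse round trip reproduces them exactly
#' within floating-point formatting error.
#'
#' @param indices Index tibble (columns `accession`, `description`, residue
#'   columns).
#' @param file Output path or connection.
#' @return `file`, invisibly.
#' @export
write_aaindex <- function(indices, file) {
  check_aaindex(indices)
  fmt_row <- function(x) paste(sprintf("%11.10g", x), collapse = " ")
  lines <- unlist(map(seq_len(nrow(indices)), function(i) {
    vals <- as.numeric(indices[i, AA_ALPHABET])
    names(vals) <- AA_ALPHABET
    c(paste("H", indices$accession[i]),
      paste("D", indices$description[i]),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("  ", fmt_row(vals[AAINDEX_ROW1])),
      paste0("  ", fmt_row(vals[AAINDEX_ROW2])),
      "//")
  }))
  writeLines(lines, file)
  invisible(file)
}

#' Standardize index values across the 20 residues
#'
#' Centers and scales each index to mean 0 and population standard deviation
#' 1 over its 20 residue values. This is the pre-conditioning applied to an
#' index before its Moreau-Broto autocorrelation is computed, following the
#' usual convention for autocorrelation descriptors; raw values are kept for
#' the per-window property means, which are min-max normalized downstream.
#'
#' @param indices Index tibble.
#' @return Index tibble of the same shape with standardized values.
#' @examples
#' idx <- synthesize_indices(3, seed = 1)
#' std <- standardize_indices(idx)
#' rowMeans(as.matrix(std[, c("A", "C", "D")])) # near 0 over all 20 columns
#' @export
standardize_indices <- function(indices) {
  check_aaindex(indices)
  vals <- as.matrix(indices[, AA_ALPHABET])
  mu <- rowMeans(vals)
  sigma <- sqrt(rowMeans((vals - mu)^2))
  degenerate <- sigma < .Machine$double.eps * 20
  if (any(degenerate)) {
    abort(sprintf(
      "Cannot standardize constant (zero-variance) index: %s",
      paste(indices$accession[degenerate], collapse = ", ")))
  }
  std <- (vals - mu) / sigma
  out <- indices
  out[, AA_ALPHABET] <- as.data.frame(std)
  out
}

check_aaindex <- function(indices) {
  if (!is.data.frame(indices) ||
      !all(c("accession", AA_ALPHABET) %in% names(indices))) {
    abort(paste("`indices` must be a tibble with columns 'accession',",
                "'description' and the 20 residue columns."))
  }
  vals <- as.matrix(indices[, AA_ALPHABET])
  if (nrow(indices) > 0 && !all(is.finite(vals))) {
    abort("Index values must all be finite.")
  }
  if (anyDuplicated(indices$accession)) {
    abort("Accessions must be unique within an index collection.")
  }
  invisible(indices)
}

#' Per-residue atomic composition table
#'
#' Counts of carbon, hydrogen, nitrogen, oxygen and sulphur atoms for each of
#' the 20 standard residues in their dehydrated, in-chain form (the residue
#' molecular formula, i.e. the free amino acid minus one water). No terminal
#' water is added when windows are summed: a hexmer is a fragment of a chain,
#' and composition stays invariant under any within-window shuffle either
#' way.
#'
#' @return A tibble with columns `residue`, `C`, `H`, `N`, `O`, `S`.
#' @examples
#' atomic_table() # Gly row: C2 H3 N1 O1 S0
#' @export
atomic_table <- function() {
  tb <- tibble(
    residue = c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    C = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
    H = c(5, 12, 6, 5, 5, 7, 8, 3, 7, 11, 11, 12, 9, 9, 7, 5, 7, 10, 9, 9),
    N = c(1, 4, 2, 1, 1, 1, 2, 1, 3, 1, 1, 2, 1, 1, 1, 1, 1, 2, 1, 1),
    O = c(1, 1, 2, 3, 1, 3, 2, 1, 1, 1, 1, 1, 1, 1, 1, 2, 2, 1, 2, 1),
    S = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0)
  )
  arrange(tb, .data$residue)
}
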