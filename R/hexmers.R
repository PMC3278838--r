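#' Cut protein sequences into six-residue sliding windows
#'
#' Slides a window of `window` residues (default 6, the hexmer unit of
#' amyloid-fibril prediction) along each sequence with step 1, yielding
#' `L - window + 1` windows for a clean length-`L` sequence. Windows that
#' contain any character outside the 20-letter standard alphabet are skipped
#' and counted rather than imputed.
#'
#' With `regions`, each window is labeled `1` if it lies entirely inside a
#' positive region of its parent sequence and `0` otherwise. Window origins
#' are 0-based and regions are half-open `[start, end)`, following BED
#' conventions. Without `regions` no `label` column is produced.
#'
#' @param sequences Named character vector of residue strings, or a data
#'   frame with columns `seq_id` and `sequence`.
#' @param regions Optional data frame with columns `seq_id`, `start`, `end`
#'   giving positive intervals.
#' @param window Window width; must be at least 1.
#' @return Tibble with columns `seq_id`, `start` (0-based offset),
#'   `sequence`, and `label` when `regions` is supplied. The number of
#'   windows dropped for non-standard residues is attached as attribute
#'   `"skipped_windows"`.
#' @examples
#' sliding_hexmers(c(p1 = "MKVIFLAG"))
#' sliding_hexmers(c(p1 = "MKVIFLAG"),
#'                 regions = data.frame(seq_id = "p1", start = 0, end = 6))
#' @export
sliding_hexmers <- function(sequences, regions = NULL, window = 6L) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("seq_id", "sequence") %in% names(sequences)))
    seqs <- stats::setNames(as.character(sequences$sequence),
                            sequences$seq_id)
  } else {
    seqs <- sequences
    if (is.null(names(seqs))) {
      names(seqs) <- paste0("seq", seq_along(seqs))
    }
  }
  window <- as.integer(window)
  if (window < 1L) abort("`window` must be a positive integer.")

  per_seq <- imap(seqs, function(s, id) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < window) {
      return(tibble(seq_id = character(), start = integer(),
                    sequence = character()))
    }
    starts <- 0:(L - window)
    tibble(seq_id = id, start = starts,
           sequence = substring(s, starts + 1L, starts + window))
  })
  out <- bind_rows(per_seq)

  n_skipped <- 0L
  if (nrow(out) > 0) {
    ok <- !grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                 out$sequence)
    n_skipped <- sum(!ok)
    out <- out[ok, , drop = FALSE]
  }

  if (!is.null(regions) && nrow(out) > 0) {
    stopifnot(all(c("seq_id", "start", "end") %in% names(regions)))
    out$label <- map2_dbl(out$seq_id, out$start, function(id, s0) {
      hit <- regions$seq_id == id &
        regions$start <= s0 & (s0 + window) <= regions$end
      as.numeric(any(hit))
    })
    out$label <- as.integer(out$label)
  } else if (!is.null(regions)) {
    out$label <- integer()
  }
  attr(out, "skipped_windows") <- n_skipped
  out
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a tidy
#' two-column tibble ready for [sliding_hexmers()].
#'
#' @param file Path to a FASTA file.
#' @return Tibble with columns `seq_id` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_fasta() requires the Biostrings package.")
  }
  set <- Biostrings::readAAStringSet(file)
  tibble(seq_id = sub("\\s.*$", "", names(set)),
         sequence = as.character(set))
}

#' Read or write a labeled hexmer table
#'
#' Hexmer tables are TSV files with a header row: first column `sequence`,
#' optional `label` (0/1) column, plus any extra columns such as `seq_id`
#' and `start`.
#'
#' @param file Path to a TSV file.
#' @return [read_hexmers()]: a tibble; [write_hexmers()]: `file`, invisibly.
#' @export
read_hexmers <- function(file) {
  out <- as_tibble(read.delim(file, sep = "\t", stringsAsFactors = FALSE))
  if (!"sequence" %in% names(out)) {
    abort("Hexmer table must have a 'sequence' column.")
  }
  if ("label" %in% names(out)) {
    if (!all(out$label %in% c(0L, 1L))) {
      abort("Hexmer labels must be 0 or 1.")
    }
    out$label <- as.integer(out$label)
  }
  out
}

#' @rdname read_hexmers
#' @param hexmers Tibble with a `sequence` column.
#' @export
write_hexmers <- function(hexmers, file) {
  write.table(hexmers, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
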