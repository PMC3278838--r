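demo_aaindex_file <- function() {
  system.file("extdata", "aaindex_demo.txt", package = "amyhex")
}

demo_indices <- function() {
  suppressMessages(read_aaindex(demo_aaindex_file()))
}

aa_alphabet <- function() {
  sort(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
}

# Random hexmers over the standard alphabet.
random_hexmers <- function(n, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(aa_alphabet(), 6, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# An index tibble built from explicit per-residue values.
index_from_values <- function(accession, values) {
  stopifnot(length(values) == 20)
  tb <- tibble::tibble(accession = accession, description = "test index")
  tb[aa_alphabet()] <- as.list(values[aa_alphabet()])
  tb
}

# A small linearly separable labeled feature tibble.
separable_data <- function(n_per_class = 30, p = 4, gap = 4, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c(1L, 0L), each = n_per_class)
    mat <- matrix(rnorm(2 * n_per_class * p), ncol = p)
    mat[, 1] <- mat[, 1] + ifelse(label == 1L, gap / 2, -gap / 2)
    colnames(mat) <- paste0("f", seq_len(p))
    dplyr::bind_cols(tibble::tibble(label = label),
                     tibble::as_tibble(as.data.frame(mat)))
  })
}
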