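# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and an integer offset.
# Kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 59999) * 31627 + as.numeric(offset) * 7919 + 17
  as.integer(s %% 2147483647)
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, width) {
  stringi::stri_rand_strings(n, width, pattern = "[ACGT]")
}

# Convert a wide count tibble (barcode + one column per sample) to an
# integer-or-numeric matrix with barcode rownames.
counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "barcode" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "barcode")])
  rownames(m) <- counts$barcode
  if (anyNA(m)) abort("count table contains missing values", class = "barseqfit_input_error")
  m
}

matrix_to_counts <- function(m) {
  out <- as_tibble(m)
  out <- dplyr::bind_cols(tibble(barcode = rownames(m)), out)
  out
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive scalar", name),
          class = "barseqfit_input_error")
  }
  invisible(x)
}
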