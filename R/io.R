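# Tab-separated file formats. All files are UTF-8, tab-separated, no
# quoting; write-then-read is the identity on every field.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s file is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "barseqfit_input_error")
  }
  invisible(df)
}

#' Read and write barcode pool files
#'
#' Pool TSV columns: `barcode scaffold strand position locus orf_fraction`;
#' `orf_fraction` is empty for intergenic strains.  Unknown extra columns
#' are preserved.
#'
#' @param path File path.
#' @param pool Pool tibble.
#' @return `read_pool()` returns the pool tibble; `write_pool()` returns
#'   `path` invisibly.
#' @export
read_pool <- function(path) {
  pool <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(pool, c("barcode", "scaffold", "strand", "position",
                          "locus", "orf_fraction"), "pool")
  dup <- pool$barcode[duplicated(pool$barcode)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate barcode in pool: %s", dup[1]),
          class = "barseqfit_input_error")
  }
  bad <- xor(pool$locus == "intergenic", is.na(pool$orf_fraction))
  if (any(bad)) {
    abort("orf_fraction must be present exactly for genic strains",
          class = "barseqfit_input_error")
  }
  pool
}

#' @rdname read_pool
#' @export
write_pool <- function(pool, path) {
  readr::write_tsv(pool, path, progress = FALSE)
  invisible(path)
}

#' Read and write barcode count tables
#'
#' Counts TSV: header `barcode <sample_id>...`, nonnegative integer
#' entries.
#'
#' @param path File path.
#' @param counts Count tibble.
#' @return `read_counts()` returns the count tibble.
#' @export
read_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(counts, "barcode", "counts")
  dup <- counts$barcode[duplicated(counts$barcode)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate barcode in counts: %s", dup[1]),
          class = "barseqfit_input_error")
  }
  for (col in setdiff(names(counts), "barcode")) {
    neg <- which(counts[[col]] < 0)
    if (length(neg) > 0) {
      abort(sprintf("negative count at row %d, column '%s'", neg[1], col),
            class = "barseqfit_input_error")
    }
  }
  counts
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read and write sample sheets
#'
#' Sample sheet TSV columns:
#' `sample_id condition passage replicate is_reference`.  The
#' `(condition, passage, replicate)` triples must be unique and the
#' reference flag must mark exactly the control passage-1 group.
#'
#' @param path File path.
#' @param sheet Sample sheet tibble.
#' @return `read_sheet()` returns the sheet tibble.
#' @export
read_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             passage = readr::col_integer(),
                             replicate = readr::col_character(),
                             is_reference = readr::col_logical(),
                             .default = readr::col_character()
                           ))
  require_columns(sheet, c("sample_id", "condition", "passage",
                           "replicate", "is_reference"), "sample sheet")
  validate_sheet(sheet)
  sheet
}

validate_sheet <- function(sheet) {
  key <- paste(sheet$condition, sheet$passage, sheet$replicate)
  if (anyDuplicated(key) > 0) {
    abort("duplicate (condition, passage, replicate) triple in sample sheet",
          class = "barseqfit_input_error")
  }
  expected_ref <- sheet$condition == "control" & sheet$passage == 1L
  if (!identical(unname(sheet$is_reference), unname(expected_ref))) {
    abort("is_reference must mark exactly the control passage-1 group",
          class = "barseqfit_input_error")
  }
  invisible(sheet)
}

#' @rdname read_sheet
#' @export
write_sheet <- function(sheet, path) {
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Read and write truth-label tables
#'
#' Truth TSV columns: `locus class growth_penalty capture_p1 ...`.
#'
#' @param path File path.
#' @param truth Truth tibble from [assign_gene_classes()].
#' @return `read_truth()` returns the truth tibble.
#' @export
read_truth <- function(path) {
  truth <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(truth, c("locus", "class", "growth_penalty"), "truth labels")
  bad <- setdiff(truth$class, PHENOTYPE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("unknown phenotype class(es) in truth file: ",
                 paste(bad, collapse = ", ")),
          class = "barseqfit_input_error")
  }
  if (anyDuplicated(truth$locus) > 0) {
    abort("duplicate locus in truth labels", class = "barseqfit_input_error")
  }
  truth
}

#' @rdname read_truth
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}
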