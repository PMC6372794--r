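#' Flanking-sequence specification for barcode extraction
#'
#' Describes where the random barcode sits inside an amplicon read: the
#' constant sequence immediately before it (`pre`), the constant sequence
#' immediately after it (`post`), the barcode length, and the per-flank
#' Hamming mismatch budget.  The flanks are configuration, not asserted
#' biology: real primer designs vary between library constructions.
#'
#' @param pre Constant DNA immediately upstream of the barcode.
#' @param post Constant DNA immediately downstream of the barcode.
#' @param barcode_length Length of the random barcode (default 20).
#' @param max_flank_mismatches Hamming mismatches tolerated per flank
#'   (default 0; no indels).
#' @return A `flank_spec` list.
#' @examples
#' flank_spec()
#' @export
flank_spec <- function(pre = "GATGTCCACGAGGTCTCT",
                       post = "CGTACGCTGCAGGTCGAC",
                       barcode_length = 20,
                       max_flank_mismatches = 0) {
  if (!nzchar(pre) || !nzchar(post)) {
    abort("flank sequences must be nonempty", class = "barseqfit_input_error")
  }
  if (barcode_length < 1) {
    abort("`barcode_length` must be >= 1", class = "barseqfit_input_error")
  }
  if (max_flank_mismatches < 0) {
    abort("`max_flank_mismatches` must be nonnegative", class = "barseqfit_input_error")
  }
  structure(
    list(pre = toupper(pre), post = toupper(post),
         barcode_length = as.integer(barcode_length),
         max_flank_mismatches = as.integer(max_flank_mismatches)),
    class = "flank_spec"
  )
}

mutate_reads <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  widths <- stringr::str_length(reads)
  n_err <- stats::rbinom(length(reads), widths, error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(widths[i], n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
    }
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Write simulated FASTQ reads for each sample
#'
#' Expands a count table into per-sample FASTQ files.  Each read is a random
#' 4-nt stagger, the `pre` flank, the barcode, the `post` flank, and a random
#' tail, with constant Phred+33 quality.  Exactly `count` copies of each
#' barcode are emitted per sample, in seeded shuffled order; an optional
#' per-base substitution error rate can corrupt reads.
#'
#' @param counts Count tibble (`barcode` + one column per sample).
#' @param pool Barcode pool; every counted barcode must appear in it.
#' @param flanks A [flank_spec()]; its barcode length must match the pool.
#' @param dir Output directory for the FASTQ files.
#' @param seed Integer seed.
#' @param error_rate Per-base substitution probability (default 0).
#' @param tail_length Length of the random 3' tail (default 15).
#' @return A tibble with `sample_id`, `path`, `n_reads`.
#' @export
emit_reads <- function(counts, pool, flanks, dir, seed,
                       error_rate = 0, tail_length = 15) {
  stopifnot(inherits(flanks, "flank_spec"))
  m <- counts_to_matrix(counts)
  if (!all(rownames(m) %in% pool$barcode)) {
    abort("count table contains barcodes absent from the pool",
          class = "barseqfit_input_error")
  }
  bc_len <- unique(stringr::str_length(pool$barcode))
  if (length(bc_len) != 1 || bc_len != flanks$barcode_length) {
    abort("flank spec barcode_length does not match pool barcode length",
          class = "barseqfit_input_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  out <- purrr::imap(
    setNames(seq_len(ncol(m)), colnames(m)),
    function(j, sid) {
      withr::with_seed(derive_seed(seed, 1000L + j), {
        cnt <- m[, j]
        barcodes <- rep(rownames(m), cnt)
        n <- length(barcodes)
        path <- file.path(dir, paste0(sid, ".fastq"))
        if (n == 0) {
          writeLines(character(0), path)
          return(tibble(sample_id = sid, path = path, n_reads = 0L))
        }
        barcodes <- barcodes[sample.int(n)]
        reads <- paste0(random_dna(n, 4L), flanks$pre, barcodes, flanks$post,
                        random_dna(n, tail_length))
        reads <- mutate_reads(reads, error_rate)
        qual <- strrep("I", stringr::str_length(reads))
        ids <- sprintf("@%s:%d", sid, seq_len(n))
        fastq <- character(4L * n)
        fastq[seq(1, by = 4, length.out = n)] <- ids
        fastq[seq(2, by = 4, length.out = n)] <- reads
        fastq[seq(3, by = 4, length.out = n)] <- "+"
        fastq[seq(4, by = 4, length.out = n)] <- qual
        writeLines(fastq, path)
        tibble(sample_id = sid, path = path, n_reads = n)
      })
    }
  )
  dplyr::bind_rows(out)
}
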