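# Barcode extraction from amplicon reads.
#
# Matching rule: the barcode is the fixed-length substring between a
# placement of `pre` and a placement of `post` starting exactly
# barcode_length after pre's end, each flank allowed up to
# max_flank_mismatches Hamming mismatches (no indels). Placements are
# scanned left to right and the leftmost valid one wins. A barcode
# containing non-ACGT characters is discarded (counted in QC).

hamming_leq <- function(a, b, max_mm) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (max_mm == 0) return(a == b)
  av <- utf8ToInt(a)
  bv <- utf8ToInt(b)
  sum(av != bv) <= max_mm
}

extract_barcode_one <- function(read, flanks) {
  lp <- nchar(flanks$pre)
  lq <- nchar(flanks$post)
  bl <- flanks$barcode_length
  mm <- flanks$max_flank_mismatches
  last_start <- nchar(read) - (lp + bl + lq) + 1L
  if (last_start < 1L) return(NA_character_)
  for (i in seq_len(last_start)) {
    if (!hamming_leq(substr(read, i, i + lp - 1L), flanks$pre, mm)) next
    pstart <- i + lp + bl
    if (!hamming_leq(substr(read, pstart, pstart + lq - 1L), flanks$post, mm)) next
    bc <- substr(read, i + lp, i + lp + bl - 1L)
    if (grepl("^[ACGT]+$", bc)) return(bc)
    return(NA_character_)
  }
  NA_character_
}

#' Extract barcodes from read sequences
#'
#' Vectorized over reads.  Returns the barcode for each read, or `NA` where
#' no valid flank placement exists or the barcode contains ambiguous bases.
#' Absence is a value, never an error.
#'
#' @param reads Character vector of read sequences.
#' @param flanks A [flank_spec()].
#' @return Character vector of barcodes (`NA` where extraction failed).
#' @examples
#' fl <- flank_spec(pre = "ACGG", post = "TTAC", barcode_length = 4)
#' extract_barcode(c("TTACGGAAAATTACGG", "ACGGAAAA"), fl)
#' @export
extract_barcode <- function(reads, flanks) {
  stopifnot(inherits(flanks, "flank_spec"))
  if (length(reads) == 0) return(character(0))
  out <- rep(NA_character_, length(reads))

  if (flanks$max_flank_mismatches == 0) {
    # fast path: leftmost exact pre occurrence, then verify post; reads
    # where that placement fails fall through to the full scan.
    lp <- nchar(flanks$pre)
    bl <- flanks$barcode_length
    loc <- stringi::stri_locate_first_fixed(reads, flanks$pre)[, "end"]
    cand <- !is.na(loc)
    bc <- stringi::stri_sub(reads[cand], loc[cand] + 1L, loc[cand] + bl)
    post_obs <- stringi::stri_sub(reads[cand], loc[cand] + bl + 1L,
                                  loc[cand] + bl + nchar(flanks$post))
    ok <- post_obs == flanks$post & stringi::stri_detect_regex(bc, "^[ACGT]+$") &
      stringi::stri_length(bc) == bl
    out[which(cand)[ok]] <- bc[ok]
    # ambiguous barcode at a valid placement is a definitive miss
    miss_def <- post_obs == flanks$post & stringi::stri_length(bc) == bl & !ok
    # no exact pre occurrence at all -> no placement can exist
    pending <- which(cand)[!ok & !miss_def]
  } else {
    pending <- seq_along(reads)
  }
  for (i in pending) {
    out[i] <- extract_barcode_one(reads[i], flanks)
  }
  out
}

read_fastq_sequences <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) return(character(0))
  if (length(lines) %% 4 != 0) {
    abort(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                  path, length(lines)),
          class = "barseqfit_input_error")
  }
  n <- length(lines) / 4
  seqs <- lines[seq(2, by = 4, length.out = n)]
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0) {
    abort(sprintf("malformed FASTQ record %d in '%s': sequence and quality lengths differ",
                  bad[1], path),
          class = "barseqfit_input_error")
  }
  seqs
}

#' Count barcodes in one FASTQ sample
#'
#' Extracts barcodes from every read of a 4-line-record FASTQ file and
#' tallies them, reporting QC statistics alongside.
#'
#' @param fastq Path to a FASTQ file.
#' @param flanks A [flank_spec()].
#' @return A list with `counts` (tibble `barcode`, `count`, sorted by
#'   barcode) and `stats` (tibble `total_reads`, `reads_with_barcode`,
#'   `distinct_barcodes`).
#' @export
count_sample <- function(fastq, flanks) {
  seqs <- read_fastq_sequences(fastq)
  barcodes <- extract_barcode(seqs, flanks)
  found <- barcodes[!is.na(barcodes)]
  tab <- table(found)
  counts <- tibble(barcode = as.character(names(tab) %||% character(0)),
                   count = as.integer(tab)) |>
    arrange(.data$barcode)
  list(
    counts = counts,
    stats = tibble(
      total_reads = length(seqs),
      reads_with_barcode = length(found),
      distinct_barcodes = nrow(counts)
    )
  )
}

#' Assemble per-sample barcode counts into a pool-indexed count table
#'
#' Restricts each sample's tally to the barcodes of the pool (zero-filling
#' unobserved pool barcodes, so downstream pseudocount math is well
#' defined) and reports, per sample, the reads assigned to barcodes absent
#' from the pool.
#'
#' @param per_sample_counts Named list of count tibbles (as produced by
#'   [count_sample()]`$counts`), one per sample; names are sample ids.
#' @param pool Barcode pool tibble.
#' @param sheet Sample sheet; every counted sample must appear in it.
#' @return List with `counts` (tibble, `barcode` + one column per sheet
#'   sample) and `unmapped` (tibble `sample_id`, `unmapped_reads`,
#'   `unmapped_fraction`).
#' @export
assemble_count_table <- function(per_sample_counts, pool, sheet) {
  extra <- setdiff(names(per_sample_counts), sheet$sample_id)
  if (length(extra) > 0) {
    abort(paste0("sample(s) not in sample sheet: ", paste(extra, collapse = ", ")),
          class = "barseqfit_input_error")
  }
  missing <- setdiff(sheet$sample_id, names(per_sample_counts))
  if (length(missing) > 0) {
    abort(paste0("no counts provided for sample(s): ", paste(missing, collapse = ", ")),
          class = "barseqfit_input_error")
  }
  m <- matrix(0L, nrow = nrow(pool), ncol = nrow(sheet),
              dimnames = list(pool$barcode, sheet$sample_id))
  unmapped <- purrr::map(sheet$sample_id, function(sid) {
    tab <- per_sample_counts[[sid]]
    idx <- match(tab$barcode, pool$barcode)
    hit <- !is.na(idx)
    m[idx[hit], sid] <<- as.integer(tab$count[hit])
    total <- sum(tab$count)
    tibble(
      sample_id = sid,
      unmapped_reads = as.integer(sum(tab$count[!hit])),
      unmapped_fraction = if (total > 0) sum(tab$count[!hit]) / total else 0
    )
  })
  list(counts = matrix_to_counts(m), unmapped = dplyr::bind_rows(unmapped))
}

#' Share of reads in the most abundant barcodes
#'
#' Ranks barcodes by descending count (ties broken lexicographically by
#' barcode), takes the top `ceiling(p/100 * B)` of the `B` pool barcodes,
#' and returns the fraction of the sample's reads they hold.  A routine QC
#' statistic for pooled libraries: a high share flags takeover by a few
#' clones during passaging.
#'
#' @param sample_counts Tibble with `barcode` and `count` covering all pool
#'   barcodes (zeros included), or a named count vector.
#' @param p Percentile, in percent (default 1).
#' @return Fraction in `[0, 1]`.
#' @examples
#' x <- tibble::tibble(barcode = sprintf("b%02d", 1:10), count = 10:1)
#' top_percentile_share(x, p = 25)  # (10 + 9 + 8) / 55
#' @export
top_percentile_share <- function(sample_counts, p = 1) {
  if (is.numeric(sample_counts)) {
    sample_counts <- tibble(barcode = names(sample_counts),
                            count = as.numeric(sample_counts))
  }
  total <- sum(sample_counts$count)
  if (total <= 0) {
    abort("sample has zero total reads", class = "barseqfit_input_error")
  }
  b <- nrow(sample_counts)
  k <- ceiling(p / 100 * b)
  ord <- order(-sample_counts$count, sample_counts$barcode)
  sum(sample_counts$count[ord[seq_len(min(k, b))]]) / total
}
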