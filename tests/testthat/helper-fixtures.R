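# Programmatic fixtures used across test files.

# A minimal sample sheet: n_ref control passage-1 replicates (the reference
# group) plus the given non-reference (condition, passage) cells, one
# replicate each unless reps > 1.
make_sheet <- function(n_ref = 2, cells = list(c("cheesecloth", 1)), reps = 1) {
  rows <- list(tibble::tibble(
    sample_id = sprintf("ctrl_p1_%s", LETTERS[seq_len(n_ref)]),
    condition = "control", passage = 1L,
    replicate = LETTERS[seq_len(n_ref)], is_reference = TRUE
  ))
  for (cell in cells) {
    cond <- cell[[1]]
    pas <- as.integer(cell[[2]])
    if (cond == "control" && pas == 1L) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample_id = sprintf("%s_p%d_%s",
                          ifelse(cond == "cheesecloth", "cheese", "ctrl"),
                          pas, LETTERS[seq_len(reps)]),
      condition = cond, passage = pas,
      replicate = LETTERS[seq_len(reps)], is_reference = FALSE
    )
  }
  dplyr::bind_rows(rows)
}

# Random pool + counts + sheet for fitness testing. Counts are integers in
# [min_count, max_count]; orf fractions span the full (0,1) so the central
# window is exercised; a couple of strains sit below typical reference
# thresholds when min_count is 0.
random_fitness_fixture <- function(seed, n_bc = 10, n_genes = 3,
                                   n_nonref = 2, n_ref = 2,
                                   min_count = 0, max_count = 200) {
  withr::with_seed(seed, {
    barcodes <- sprintf("bc%02d%s", seq_len(n_bc),
                        stringi::stri_rand_strings(n_bc, 6, "[ACGT]"))
    loci <- c(sprintf("gene_%02d", seq_len(n_genes)), "intergenic")
    pool <- tibble::tibble(
      barcode = barcodes,
      scaffold = "chr1",
      strand = sample(c("+", "-"), n_bc, replace = TRUE),
      position = sample.int(10000, n_bc),
      locus = sample(loci, n_bc, replace = TRUE,
                     prob = c(rep(0.3, n_genes), 0.1))
    )
    pool$orf_fraction <- ifelse(pool$locus == "intergenic", NA_real_,
                                runif(n_bc))
    cells <- list(c("cheesecloth", 1), c("cheesecloth", 2), c("control", 2))
    sheet <- make_sheet(n_ref = n_ref, cells = cells[seq_len(n_nonref)])
    m <- matrix(
      sample(min_count:max_count, n_bc * nrow(sheet), replace = TRUE),
      nrow = n_bc, dimnames = list(barcodes, sheet$sample_id)
    )
    counts <- dplyr::bind_cols(tibble::tibble(barcode = barcodes),
                               tibble::as_tibble(m))
    list(pool = pool, counts = counts, sheet = sheet, m = m)
  })
}

# Small simulation configuration for pipeline-level tests.
small_sim_config <- function(n_genes = 60, reads_per_sample = 3000, ...) {
  sim_config(
    n_genes = n_genes, insertions_per_gene_mean = 2, intergenic_fraction = 0.1,
    reads_per_sample = reads_per_sample,
    class_proportions = c(neutral = 0.70, nonadhesive_strong = 0.10,
                          nonadhesive_mild = 0.05, hyperadhesive = 0.05,
                          recovery = 0.05, growth_defect = 0.05),
    ...
  )
}

# Normalized-profile tibble from a named list of g vectors.
norm_from_list <- function(profiles) {
  dplyr::bind_rows(lapply(names(profiles), function(l) {
    tibble::tibble(locus = l, passage = seq_along(profiles[[l]]),
                   g = profiles[[l]])
  }))
}
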