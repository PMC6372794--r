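#' Build a synthetic barcode pool
#'
#' Generates the table mapping each random 20-nt barcode to a unique
#' insertion site and gene assignment, emulating a mapped randomly barcoded
#' transposon library.  Each gene receives a zero-truncated
#' Poisson(`insertions_per_gene_mean`) number of insertion strains with
#' `orf_fraction` (position of the insertion along the ORF, 0 = start codon
#' side) drawn uniformly on (0, 1).  Additional strains are placed between
#' genes so that the configured fraction of all strains has no gene
#' assignment (`locus == "intergenic"`, `orf_fraction` missing).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the pool is deterministic given the seed.
#' @return A tibble with columns `barcode`, `scaffold`, `strand`,
#'   `position`, `locus`, `orf_fraction`.
#' @examples
#' pool <- build_pool(sim_config(n_genes = 5), seed = 1)
#' dplyr::count(pool, locus == "intergenic")
#' @export
build_pool <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(derive_seed(seed, 1L), {
    n_genes <- config$n_genes
    lambda <- config$insertions_per_gene_mean

    # zero-truncated Poisson via redraw of zeros
    n_strains <- rpois(n_genes, lambda)
    while (any(n_strains == 0)) {
      idx <- which(n_strains == 0)
      n_strains[idx] <- rpois(length(idx), lambda)
    }

    orf_len <- 900L
    spacer <- 300L
    gene_start <- (seq_len(n_genes) - 1L) * (orf_len + spacer) + spacer + 1L
    loci <- sprintf("locus_%05d", seq_len(n_genes))

    locus <- rep(loci, n_strains)
    start <- rep(gene_start, n_strains)
    orf_fraction <- runif(sum(n_strains))
    genic <- tibble(
      scaffold = "chr1",
      strand = sample(c("+", "-"), sum(n_strains), replace = TRUE),
      position = as.integer(start + floor(orf_fraction * orf_len)),
      locus = locus,
      orf_fraction = orf_fraction
    )

    n_inter <- round(sum(n_strains) * config$intergenic_fraction /
                       (1 - config$intergenic_fraction))
    if (n_inter > 0) {
      spacer_idx <- sample.int(n_genes, n_inter, replace = TRUE)
      inter <- tibble(
        scaffold = "chr1",
        strand = sample(c("+", "-"), n_inter, replace = TRUE),
        position = as.integer((spacer_idx - 1L) * (orf_len + spacer) +
                                sample.int(spacer, n_inter, replace = TRUE)),
        locus = "intergenic",
        orf_fraction = NA_real_
      )
      genic <- dplyr::bind_rows(genic, inter)
    }

    n_total <- nrow(genic)
    barcodes <- random_dna(n_total, 20L)
    attempts <- 0L
    while (anyDuplicated(barcodes) > 0) {
      attempts <- attempts + 1L
      if (attempts > 100L) {
        abort("barcode space exhausted: could not draw unique barcodes",
              class = "barseqfit_internal_error")
      }
      dup <- duplicated(barcodes)
      barcodes[dup] <- random_dna(sum(dup), 20L)
    }

    dplyr::bind_cols(tibble(barcode = barcodes), genic)
  })
}

#' Assign planted phenotype classes to genes
#'
#' Draws a phenotype class for every gene in proportion to
#' `class_proportions` and records the per-passage capture schedule and
#' growth penalty each gene's strains will experience in the simulation.
#' Intergenic strains are always treated as neutral and are not listed here.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble of truth labels: `locus`, `class`, `growth_penalty`,
#'   and capture columns `capture_p1` ... `capture_p<n_passages>`.
#' @export
assign_gene_classes <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  props <- config$class_proportions
  if (abs(sum(props) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1", class = "barseqfit_input_error")
  }
  withr::with_seed(derive_seed(seed, 2L), {
    classes <- sample(names(props), config$n_genes, replace = TRUE, prob = props)
  })
  schedules <- vapply(classes, function(cl) capture_schedule_for(config, cl),
                      numeric(config$n_passages))
  out <- tibble(
    locus = sprintf("locus_%05d", seq_len(config$n_genes)),
    class = classes,
    growth_penalty = unname(config$growth_penalty[classes])
  )
  cap <- t(schedules)
  colnames(cap) <- sprintf("capture_p%d", seq_len(config$n_passages))
  dplyr::bind_cols(out, as_tibble(cap))
}

# Per-strain capture schedule matrix (strains x passages) and growth
# penalty vector, aligned with pool rows. Intergenic strains behave as
# wild type (neutral).
strain_dynamics <- function(pool, truth, config) {
  if (!setequal(setdiff(pool$locus, "intergenic"), truth$locus)) {
    abort("pool and truth labels do not share the same gene universe",
          class = "barseqfit_input_error")
  }
  cap_cols <- sprintf("capture_p%d", seq_len(config$n_passages))
  idx <- match(pool$locus, truth$locus)
  cap <- as.matrix(truth[cap_cols])[idx, , drop = FALSE]
  pen <- truth$growth_penalty[idx]
  inter <- is.na(idx)
  cap[inter, ] <- matrix(rep(capture_schedule_for(config, "neutral"),
                             each = sum(inter)), nrow = sum(inter))
  pen[inter] <- config$growth_penalty[["neutral"]]
  list(capture = cap, penalty = pen)
}
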