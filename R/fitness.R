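#' Parameters of the strain/gene fitness calculation
#'
#' @param pseudocount Pseudocount `ps` added to every barcode count; it also
#'   enters the depth as `D + ps * B` (`B` = number of pool barcodes) so
#'   frequencies stay normalized.  The default 0.5 is a Jeffreys-style
#'   choice; `ps = 0` gives the raw log ratio (and is required for exact
#'   depth invariance).
#' @param min_reference_count Strains whose summed count over the pooled
#'   reference samples falls below this are marked unusable (default 3).
#' @param central_window Closed interval of `orf_fraction` within which an
#'   insertion counts toward gene fitness (default `c(0.10, 0.90)`,
#'   endpoints inclusive): insertions in the outer 10% of an ORF often fail
#'   to disrupt the gene.
#' @param weighting Strain weighting for the gene average: `"precision"`
#'   (default) uses the delta-method inverse variance of a log count ratio,
#'   `1 / (1/(n_s + ps) + 1/(n0 + ps))`; `"reference_count"` uses
#'   `n0 + ps`; `"uniform"` uses 1.
#' @param center Per-sample centering of gene fitness: `"median"` (default)
#'   or `"none"`.
#' @return A `fitness_params` list.
#' @export
fitness_params <- function(pseudocount = 0.5,
                           min_reference_count = 3,
                           central_window = c(0.10, 0.90),
                           weighting = c("precision", "reference_count", "uniform"),
                           center = c("median", "none")) {
  weighting <- match.arg(weighting)
  center <- match.arg(center)
  if (pseudocount < 0) {
    abort("`pseudocount` must be nonnegative", class = "barseqfit_input_error")
  }
  if (min_reference_count < 0) {
    abort("`min_reference_count` must be nonnegative", class = "barseqfit_input_error")
  }
  if (length(central_window) != 2 || central_window[1] > central_window[2] ||
      central_window[1] < 0 || central_window[2] > 1) {
    abort("`central_window` must be an ordered interval within [0, 1]",
          class = "barseqfit_input_error")
  }
  structure(
    list(pseudocount = pseudocount,
         min_reference_count = min_reference_count,
         central_window = central_window,
         weighting = weighting,
         center = center),
    class = "fitness_params"
  )
}

# Pooled reference counts and depths. Reference = sum over the reference
# group samples (pooling stabilizes small counts).
reference_counts <- function(m, sheet) {
  ref_ids <- sheet$sample_id[sheet$is_reference]
  if (length(ref_ids) == 0) {
    abort("sample sheet designates no reference samples",
          class = "barseqfit_input_error")
  }
  missing <- setdiff(ref_ids, colnames(m))
  if (length(missing) > 0) {
    abort(paste0("reference sample(s) absent from counts: ",
                 paste(missing, collapse = ", ")),
          class = "barseqfit_input_error")
  }
  n0 <- rowSums(m[, ref_ids, drop = FALSE])
  list(n0 = n0, d0 = sum(n0), ref_ids = ref_ids)
}

#' Strain fitness: log2 ratio to the pooled reference
#'
#' For each barcode *i* and non-reference sample *s*, fitness is the log2
#' ratio of pseudocounted frequencies,
#' `f = log2((n_is + ps) / (D_s + ps B)) - log2((n0_i + ps) / (D0 + ps B))`,
#' where `n0_i` pools the strain's counts over the reference-group samples
#' and `D0` their summed depth.  A strain is `usable` when its pooled
#' reference count reaches `min_reference_count`.
#'
#' @param counts Count tibble (`barcode` + one column per sample); entries
#'   may be real-valued (expected counts) as well as integers.
#' @param sheet Sample sheet with an `is_reference` group.
#' @param params A [fitness_params()].
#' @return Tibble `barcode`, `sample`, `fitness`, `usable`, one row per
#'   (barcode, non-reference sample).
#' @export
strain_fitness <- function(counts, sheet, params = fitness_params()) {
  stopifnot(inherits(params, "fitness_params"))
  m <- counts_to_matrix(counts)
  validate_sheet(sheet)
  ref <- reference_counts(m, sheet)
  ps <- params$pseudocount
  b <- nrow(m)

  sample_ids <- intersect(sheet$sample_id, colnames(m))
  nonref <- setdiff(sample_ids, ref$ref_ids)
  depths <- colSums(m[, nonref, drop = FALSE])
  if (any(depths <= 0)) {
    abort(paste0("zero-depth sample(s): ",
                 paste(nonref[depths <= 0], collapse = ", ")),
          class = "barseqfit_input_error")
  }
  log_ref <- log2(ref$n0 + ps) - log2(ref$d0 + ps * b)
  f <- log2(sweep(m[, nonref, drop = FALSE] + ps, 2, depths + ps * b, "/")) - log_ref
  usable <- ref$n0 >= params$min_reference_count

  out <- tibble(
    barcode = rep(rownames(m), times = length(nonref)),
    sample = rep(nonref, each = nrow(m)),
    fitness = as.vector(f),
    usable = rep(unname(usable), times = length(nonref))
  )
  out$fitness[!out$usable] <- NA_real_
  out
}

#' Gene fitness: weighted average over central insertion strains
#'
#' Averages strain fitness over the usable strains of each gene whose
#' insertion lies in the central window of the ORF (endpoints inclusive),
#' with the weighting chosen in `params`.  Genes with no eligible strain
#' carry no value (they are absent from the result, never reported as 0).
#'
#' @param strains Strain fitness tibble from [strain_fitness()].
#' @param counts The same count tibble used for [strain_fitness()] (needed
#'   for count-based weights).
#' @param pool Barcode pool tibble.
#' @param sheet Sample sheet.
#' @param params A [fitness_params()].
#' @return Tibble `locus`, `sample`, `fitness`, `n_strains_used`.
#' @export
gene_fitness <- function(strains, counts, pool, sheet, params = fitness_params()) {
  stopifnot(inherits(params, "fitness_params"))
  m <- counts_to_matrix(counts)
  ref <- reference_counts(m, sheet)
  missing <- setdiff(pool$barcode, unique(strains$barcode))
  if (length(missing) > 0) {
    abort(paste0("pool barcode(s) absent from strain fitness table: ",
                 paste(utils::head(missing, 3), collapse = ", ")),
          class = "barseqfit_input_error")
  }
  ps <- params$pseudocount
  lo <- params$central_window[1]
  hi <- params$central_window[2]

  pool_info <- pool |>
    select("barcode", "locus", "orf_fraction") |>
    mutate(n0 = ref$n0[match(.data$barcode, rownames(m))])

  df <- strains |>
    inner_join(pool_info, by = "barcode") |>
    filter(.data$usable,
           .data$locus != "intergenic",
           .data$orf_fraction >= lo,
           .data$orf_fraction <= hi)
  if (nrow(df) == 0) {
    return(tibble(locus = character(0), sample = character(0),
                  fitness = numeric(0), n_strains_used = integer(0)))
  }
  df$n_s <- m[cbind(match(df$barcode, rownames(m)), match(df$sample, colnames(m)))]
  df$w <- switch(params$weighting,
    precision = 1 / (1 / (df$n_s + ps) + 1 / (df$n0 + ps)),
    reference_count = df$n0 + ps,
    uniform = rep(1, nrow(df))
  )
  df |>
    summarise(
      fitness = sum(.data$w * .data$fitness) / sum(.data$w),
      n_strains_used = dplyr::n(),
      .by = c("locus", "sample")
    )
}

#' Center gene fitness per sample
#'
#' Subtracts the per-sample median gene fitness from every gene in that
#' sample (`method = "median"`), so that the typical gene sits at 0 in each
#' sample — a compositional correction for shifts the log-ratio transform
#' leaves behind.  `method = "none"` is the identity.
#'
#' @param genes Gene fitness tibble from [gene_fitness()].
#' @param method `"median"` or `"none"`.
#' @return Gene fitness tibble with centered `fitness`.
#' @export
center_fitness <- function(genes, method = c("median", "none")) {
  method <- match.arg(method)
  if (method == "none") return(genes)
  n_per_sample <- genes |> filter(!is.na(.data$fitness)) |> count(.data$sample)
  if (nrow(n_per_sample) == 0 || any(n_per_sample$n < 3)) {
    abort("median centering needs at least 3 genes with values per sample",
          class = "barseqfit_input_error")
  }
  genes |>
    mutate(fitness = .data$fitness - median(.data$fitness, na.rm = TRUE),
           .by = "sample")
}
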