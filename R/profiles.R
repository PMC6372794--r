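#' Aggregate replicate gene fitness into a temporal profile grid
#'
#' Groups the non-reference samples by (condition, passage) and computes,
#' per gene and group, the replicate mean and sample standard deviation
#' (n - 1 denominator).  The reference group (control passage 1) defines
#' fitness zero, so its cell carries mean 0 and SD 0 for every gene.
#'
#' @param genes Gene fitness tibble (ideally centered; see
#'   [center_fitness()]).
#' @param sheet Sample sheet.
#' @return Tibble `locus`, `condition`, `passage`, `mean`, `sd`, `n`
#'   covering the full condition-by-passage grid for every gene.
#' @export
aggregate_replicates <- function(genes, sheet) {
  validate_sheet(sheet)
  extra <- setdiff(unique(genes$sample), sheet$sample_id)
  if (length(extra) > 0) {
    abort(paste0("gene fitness sample(s) missing from sheet: ",
                 paste(extra, collapse = ", ")),
          class = "barseqfit_input_error")
  }
  nonref <- sheet |> filter(!.data$is_reference)
  grouped <- genes |>
    inner_join(select(nonref, "sample_id", "condition", "passage"),
               by = c(sample = "sample_id")) |>
    summarise(
      mean = mean(.data$fitness),
      sd = if (dplyr::n() >= 2) sd(.data$fitness) else NA_real_,
      n = dplyr::n(),
      .by = c("locus", "condition", "passage")
    )

  empty <- nonref |>
    distinct(.data$condition, .data$passage) |>
    anti_join(distinct(grouped, .data$condition, .data$passage),
              by = c("condition", "passage"))
  if (nrow(empty) > 0) {
    abort("a (condition, passage) group has no samples with fitness values",
          class = "barseqfit_input_error")
  }

  ref_group <- sheet |> filter(.data$is_reference)
  ref_cell <- tidyr::expand_grid(
    locus = unique(grouped$locus),
    condition = unique(ref_group$condition),
    passage = unique(ref_group$passage)
  ) |>
    mutate(mean = 0, sd = 0, n = nrow(ref_group))

  dplyr::bind_rows(grouped, ref_cell) |>
    arrange(.data$locus, .data$condition, .data$passage)
}

#' Replicate-noise filter on temporal profiles
#'
#' A gene is removed when its largest replicate SD across all
#' condition-passage cells exceeds its largest absolute mean fitness across
#' the same cells — profiles whose noise dominates their signal.  Ties
#' (including the all-zero profile, since 0 > 0 is false) are kept.  Genes
#' with any cell lacking an SD (fewer than 2 replicates) cannot be
#' evaluated; they are kept and flagged.
#'
#' @param profiles Profile tibble from [aggregate_replicates()].
#' @return List with `kept` and `removed` tibbles, each carrying `locus`,
#'   `max_sd`, `max_abs_fitness`, `unevaluable`.
#' @export
sd_filter <- function(profiles) {
  per_gene <- profiles |>
    summarise(
      max_sd = if (any(is.na(.data$sd))) NA_real_ else max(.data$sd),
      max_abs_fitness = max(abs(.data$mean)),
      .by = "locus"
    ) |>
    mutate(unevaluable = is.na(.data$max_sd),
           removed = !.data$unevaluable & .data$max_sd > .data$max_abs_fitness)
  if (any(per_gene$unevaluable)) {
    inform(sprintf("sd_filter: %d gene(s) unevaluable (missing replicate SD); kept",
                   sum(per_gene$unevaluable)))
  }
  list(
    kept = per_gene |> filter(!.data$removed) |> select(-"removed"),
    removed = per_gene |> filter(.data$removed) |> select(-"removed")
  )
}

#' Condition-difference normalization of temporal profiles
#'
#' Subtracts, passage by passage, the mean control-condition fitness from
#' the mean cheesecloth fitness: `g_t = cheesecloth_t - control_t`.  Pure
#' growth effects act identically in both conditions and cancel, so `g`
#' isolates adhesion-dependent selection.  Genes with an incomplete
#' condition-passage grid are dropped with a message.
#'
#' @param profiles Profile tibble from [aggregate_replicates()].
#' @return Tibble `locus`, `passage`, `g` (log2 units).
#' @export
condition_normalize <- function(profiles) {
  n_cells <- profiles |> distinct(.data$condition, .data$passage) |> nrow()
  passages <- sort(unique(profiles$passage))
  wide <- profiles |>
    select("locus", "condition", "passage", "mean") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean")
  if (!all(c("cheesecloth", "control") %in% names(wide))) {
    abort("both conditions are required for normalization",
          class = "barseqfit_input_error")
  }
  complete <- wide |>
    filter(!is.na(.data$cheesecloth), !is.na(.data$control)) |>
    mutate(n_pass = dplyr::n(), .by = "locus") |>
    filter(.data$n_pass == length(passages))
  dropped <- setdiff(unique(profiles$locus), unique(complete$locus))
  if (length(dropped) > 0) {
    inform(sprintf("condition_normalize: dropped %d gene(s) with incomplete grids",
                   length(dropped)))
  }
  complete |>
    transmute(.data$locus, .data$passage,
              g = .data$cheesecloth - .data$control) |>
    arrange(.data$locus, .data$passage)
}

#' Rank genes by peak absolute normalized fitness and select the top k
#'
#' Scores each gene by `max_t |g_t|` over the cheesecloth passages, sorts
#' by descending score (ties broken by locus identifier), and returns the
#' first `min(k, n)` genes.
#'
#' @param norm Normalized profile tibble from [condition_normalize()].
#' @param k Number of genes to select (default 250).
#' @return Tibble `locus`, `score`, `rank`.
#' @export
rank_and_select <- function(norm, k = 250) {
  if (k < 1) abort("`k` must be >= 1", class = "barseqfit_input_error")
  scored <- norm |>
    summarise(score = max(abs(.data$g)), .by = "locus") |>
    arrange(desc(.data$score), .data$locus) |>
    mutate(rank = dplyr::row_number())
  head(scored, min(k, nrow(scored)))
}
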