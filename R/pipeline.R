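#' Run the full fitness-profiling pipeline
#'
#' Orchestrates counting (optional, from FASTQ), strain and gene fitness,
#' temporal profile construction with the replicate-SD filter,
#' condition-difference normalization, ranking, clustering, and archetype
#' labeling.  Either `counts` or `fastq` must be supplied.  All parameters
#' are recorded in a manifest so a run is reproducible from its outputs.
#'
#' @param pool Barcode pool tibble (or path to a pool TSV).
#' @param sheet Sample sheet tibble (or path).
#' @param counts Count tibble (or path); mutually exclusive with `fastq`.
#' @param fastq Named character vector of FASTQ paths (names = sample ids).
#' @param flanks A [flank_spec()] (required in FASTQ mode).
#' @param params A [fitness_params()].
#' @param top_k Genes to select by peak absolute normalized fitness.
#' @param metric,linkage,k Clustering options (see [profile_distance()] and
#'   [hierarchical_cluster()]).
#' @param thresholds An [archetype_thresholds()].
#' @param out_dir Optional directory; when given, every intermediate table
#'   plus a JSON manifest and a plain-text log are written there.
#' @return Object of class `barseq_run`: list with `counts`, `qc`,
#'   `strain_fitness`, `gene_fitness`, `profiles`, `filter`, `normalized`,
#'   `selected`, `distances`, `clusters`, `archetypes`, `manifest`.
#' @export
run_pipeline <- function(pool, sheet,
                         counts = NULL, fastq = NULL, flanks = NULL,
                         params = fitness_params(),
                         top_k = 250,
                         metric = "euclidean", linkage = "ward", k = 6,
                         thresholds = archetype_thresholds(),
                         out_dir = NULL) {
  if (is.character(pool)) pool <- read_pool(pool)
  if (is.character(sheet)) sheet <- read_sheet(sheet)
  if (is.character(counts)) counts <- read_counts(counts)
  if (top_k < 1) abort("`top_k` must be >= 1", class = "barseqfit_input_error")

  log_lines <- character(0)
  log_event <- function(stage, msg) {
    line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage, msg)
    log_lines <<- c(log_lines, line)
  }

  qc <- NULL
  if (is.null(counts)) {
    if (is.null(fastq) || is.null(flanks)) {
      abort("FASTQ mode needs `fastq` paths and a `flanks` spec",
            class = "barseqfit_input_error")
    }
    per_sample <- purrr::map(fastq, count_sample, flanks = flanks)
    assembled <- assemble_count_table(purrr::map(per_sample, "counts"),
                                      pool, sheet)
    counts <- assembled$counts
    qc <- list(
      extraction = purrr::imap(per_sample, \(x, sid) mutate(x$stats, sample_id = sid)) |>
        dplyr::bind_rows(),
      unmapped = assembled$unmapped
    )
    high <- assembled$unmapped |> filter(.data$unmapped_fraction > 0.10)
    if (nrow(high) > 0) {
      log_event("count", sprintf("unmapped-read fraction > 10%% in %d sample(s)",
                                 nrow(high)))
    }
    log_event("count", sprintf("counted %d samples from FASTQ", length(fastq)))
  } else {
    log_event("count", "counts supplied directly; counting stage skipped")
  }

  strains <- strain_fitness(counts, sheet, params)
  genes <- gene_fitness(strains, counts, pool, sheet, params)
  genes <- center_fitness(genes, method = params$center)
  log_event("fitness", sprintf("gene fitness for %d genes x %d samples",
                               dplyr::n_distinct(genes$locus),
                               dplyr::n_distinct(genes$sample)))

  profiles <- aggregate_replicates(genes, sheet)
  filt <- sd_filter(profiles)
  kept_profiles <- profiles |> filter(.data$locus %in% filt$kept$locus)
  normalized <- condition_normalize(kept_profiles)
  selected <- rank_and_select(normalized, k = top_k)
  log_event("profiles", sprintf("%d genes kept by SD filter, %d selected",
                                nrow(filt$kept), nrow(selected)))

  sel_norm <- normalized |> filter(.data$locus %in% selected$locus)
  distances <- profile_distance(sel_norm, metric = metric)
  clusters <- hierarchical_cluster(distances, linkage = linkage,
                                   k = min(k, nrow(selected)))
  archetypes <- label_archetypes(sel_norm, thresholds)
  log_event("clustering", sprintf("clustered %d genes into %d groups",
                                  nrow(selected), clusters$k))

  manifest <- list(
    input_mode = if (is.null(qc)) "counts" else "fastq",
    n_barcodes = nrow(pool),
    n_samples = nrow(sheet),
    fitness_params = unclass(params),
    top_k = top_k,
    metric = metric,
    linkage = linkage,
    k = clusters$k,
    thresholds = unclass(thresholds),
    stages_complete = c("count", "fitness", "profiles", "clustering")
  )

  run <- structure(
    list(counts = counts, qc = qc, strain_fitness = strains,
         gene_fitness = genes, profiles = profiles, filter = filt,
         normalized = normalized, selected = selected,
         distances = distances, clusters = clusters,
         archetypes = archetypes, manifest = manifest, log = log_lines),
    class = "barseq_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    readr::write_tsv(strains, file.path(out_dir, "strain_fitness.tsv"), progress = FALSE)
    readr::write_tsv(genes, file.path(out_dir, "gene_fitness.tsv"), progress = FALSE)
    readr::write_tsv(profiles, file.path(out_dir, "profiles.tsv"), progress = FALSE)
    norm_wide <- normalized |>
      tidyr::pivot_wider(names_from = "passage", values_from = "g",
                         names_prefix = "g") |>
      left_join(selected, by = "locus") |>
      mutate(kept = !is.na(.data$rank))
    readr::write_tsv(norm_wide, file.path(out_dir, "normalized_profiles.tsv"), progress = FALSE)
    assignments <- clusters$assignment |>
      left_join(archetypes, by = "locus") |>
      left_join(selected, by = "locus")
    readr::write_tsv(assignments, file.path(out_dir, "clusters.tsv"), progress = FALSE)
    readr::write_tsv(clusters$merges, file.path(out_dir, "merge_tree.tsv"), progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  run
}

#' @export
print.barseq_run <- function(x, ...) {
  cat("BarSeq serial-passage fitness run\n")
  cat(sprintf("  input mode: %s\n", x$manifest$input_mode))
  cat(sprintf("  %d barcodes, %d samples\n", x$manifest$n_barcodes, x$manifest$n_samples))
  cat(sprintf("  %d genes profiled, %d selected, %d clusters\n",
              dplyr::n_distinct(x$profiles$locus), nrow(x$selected), x$clusters$k))
  invisible(x)
}

#' @export
glance.barseq_run <- function(x, ...) {
  tibble(
    n_barcodes = x$manifest$n_barcodes,
    n_samples = x$manifest$n_samples,
    n_genes = dplyr::n_distinct(x$profiles$locus),
    n_removed_sd = nrow(x$filter$removed),
    n_selected = nrow(x$selected),
    k = x$clusters$k
  )
}

#' Score a simulated run against its planted truth
#'
#' Computes, for a pipeline run on simulated data: recall of each planted
#' class among the selected genes; the adjusted Rand index between the flat
#' clusters and the truth classes, restricted to selected planted
#' non-neutral genes; the mean absolute normalized fitness of planted
#' neutral genes (a bias measure); and the archetype-vs-truth confusion
#' table with the per-class agreement under the natural correspondence
#' (strong adhesion loss = biosynthesis, mild = modification,
#' hyperadhesive = hyperadhesive, recovery = recovery).
#'
#' @param run A `barseq_run` from [run_pipeline()].
#' @param truth Truth labels from [assign_gene_classes()].
#' @return Object of class `barseq_eval`: list with `recall` (tibble
#'   `class`, `n_planted`, `n_selected`, `recall`), `ari`, `neutral_bias`,
#'   `growth_defect_bias`, `confusion` (tibble), `archetype_agreement`.
#' @export
evaluate_against_truth <- function(run, truth) {
  stopifnot(inherits(run, "barseq_run"))
  profiled <- unique(run$normalized$locus)
  missing <- setdiff(profiled, truth$locus)
  if (length(missing) > 0) {
    abort("truth labels do not cover all profiled genes",
          class = "barseqfit_input_error")
  }
  if (nrow(run$selected) == 0) {
    abort("empty selection; nothing to evaluate", class = "barseqfit_input_error")
  }
  selected <- run$selected$locus

  recall <- truth |>
    summarise(
      n_planted = dplyr::n(),
      n_selected = sum(.data$locus %in% selected),
      .by = "class"
    ) |>
    mutate(recall = .data$n_selected / .data$n_planted)

  truth_class <- setNames(truth$class, truth$locus)
  nonneutral <- selected[truth_class[selected] != "neutral"]
  cl <- run$clusters$assignment
  cl_non <- cl |> filter(.data$locus %in% nonneutral)
  ari <- if (nrow(cl_non) >= 2) {
    mclust::adjustedRandIndex(cl_non$cluster, truth_class[cl_non$locus])
  } else {
    NA_real_
  }

  neutral_bias <- run$normalized |>
    filter(truth_class[.data$locus] == "neutral") |>
    summarise(bias = mean(abs(.data$g))) |>
    dplyr::pull(.data$bias)

  gd_bias <- run$normalized |>
    filter(truth_class[.data$locus] == "growth_defect") |>
    summarise(bias = mean(abs(.data$g)), .by = "passage")

  expected_archetype <- c(
    nonadhesive_strong = "biosynthesis",
    nonadhesive_mild = "modification",
    hyperadhesive = "hyperadhesive",
    recovery = "recovery"
  )
  arch <- run$archetypes |>
    filter(.data$locus %in% nonneutral) |>
    mutate(truth_class = unname(truth_class[.data$locus]),
           expected = unname(expected_archetype[.data$truth_class]),
           agree = !is.na(.data$expected) & .data$archetype == .data$expected)
  confusion <- arch |> count(.data$truth_class, .data$archetype)
  agreement <- if (nrow(arch) > 0) mean(arch$agree) else NA_real_

  structure(
    list(recall = recall, ari = ari, neutral_bias = neutral_bias,
         growth_defect_bias = gd_bias, confusion = confusion,
         archetype_agreement = agreement),
    class = "barseq_eval"
  )
}

#' @export
print.barseq_eval <- function(x, ...) {
  cat("Evaluation against planted truth\n")
  print(x$recall)
  cat(sprintf("  ARI (clusters vs truth, selected non-neutral): %.3f\n", x$ari))
  cat(sprintf("  neutral bias (mean |g|): %.3f\n", x$neutral_bias))
  cat(sprintf("  archetype agreement: %.3f\n", x$archetype_agreement))
  invisible(x)
}

#' @export
glance.barseq_eval <- function(x, ...) {
  tibble(
    ari = x$ari,
    neutral_bias = x$neutral_bias,
    archetype_agreement = x$archetype_agreement,
    recall_nonadhesive_strong =
      x$recall$recall[x$recall$class == "nonadhesive_strong"] %||% NA_real_
  )
}
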