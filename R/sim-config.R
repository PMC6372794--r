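#' Phenotype classes planted by the passaging simulator
#'
#' The fixed vocabulary of mutant phenotype classes the simulator can plant:
#' `neutral` strains behave like wild type; `nonadhesive_strong` strains are
#' never captured by the cloth and enrich continuously; `nonadhesive_mild`
#' strains are captured at a reduced rate; `hyperadhesive` strains are
#' captured more efficiently than wild type and deplete; `recovery` strains
#' follow a time-varying capture schedule (strong early depletion that
#' relaxes over later passages, the shape seen for smooth-LPS mutants);
#' `growth_defect` strains adhere like wild type but carry a growth penalty
#' in both conditions, the confounder that condition subtraction removes.
#'
#' @export
PHENOTYPE_CLASSES <- c(
  "neutral", "nonadhesive_strong", "nonadhesive_mild",
  "hyperadhesive", "recovery", "growth_defect"
)

#' Configuration for the serial-passaging simulator
#'
#' Bundles every tunable of the forward simulation of a pooled barcoded
#' transposon library passaged with and without an adhesion sink
#' (cheesecloth).  Defaults emulate the structure of the real experiment:
#' roughly a thousand genes with a handful of insertion strains each, two
#' conditions, five passages, three replicates, and a per-passage dilution
#' of about 15-fold (`log2(15) ~ 3.9` doublings of regrowth to saturation).
#'
#' @param n_genes Number of genes in the library.
#' @param insertions_per_gene_mean Poisson rate for the number of insertion
#'   strains per gene (conditioned to be at least 1).
#' @param intergenic_fraction Fraction of all strains carrying insertions
#'   outside any ORF (no gene assignment); must be in `[0, 1)`.
#' @param class_proportions Named numeric vector over
#'   [PHENOTYPE_CLASSES] giving the fraction of genes planted in each
#'   class; must sum to 1.
#' @param wt_capture Per-cycle probability that a wild-type-like cell is
#'   removed from the planktonic phase by the cloth.
#' @param class_capture Named list mapping each class to its per-cycle
#'   capture probability, either a scalar or a length-`n_passages` schedule.
#' @param recovery_schedule Per-passage capture probabilities for the
#'   `recovery` class; length must equal `n_passages`.
#' @param growth_penalty Named numeric vector of relative growth deficits
#'   per doubling (0 for unnamed classes).
#' @param doublings_per_cycle Doublings of regrowth per passage cycle.
#' @param n_passages Number of serial passages.
#' @param n_replicates Number of replicate passaging series.
#' @param reads_per_sample Sequencing reads drawn per sample.
#' @param abundance_lognormal_sigma Log-normal sigma of initial strain
#'   abundances (0 gives a perfectly even starting pool).
#' @param overdispersion Dirichlet-multinomial overdispersion; 0 (default)
#'   gives plain multinomial read sampling, larger values add
#'   between-library noise with concentration `reads_per_sample / overdispersion`.
#'
#' @return A `sim_config` list, validated.
#' @examples
#' cfg <- sim_config(n_genes = 50, reads_per_sample = 5000)
#' cfg$n_passages
#' @export
sim_config <- function(n_genes = 1000,
                       insertions_per_gene_mean = 3,
                       intergenic_fraction = 0.15,
                       class_proportions = c(
                         neutral = 0.90,
                         nonadhesive_strong = 0.03,
                         nonadhesive_mild = 0.02,
                         hyperadhesive = 0.02,
                         recovery = 0.02,
                         growth_defect = 0.01
                       ),
                       wt_capture = 0.6,
                       class_capture = NULL,
                       recovery_schedule = c(0.9, 0.9, 0.7, 0.5, 0.3),
                       growth_penalty = c(growth_defect = -0.15),
                       doublings_per_cycle = 3.9,
                       n_passages = 5,
                       n_replicates = 3,
                       reads_per_sample = 200000,
                       abundance_lognormal_sigma = 0.8,
                       overdispersion = 0) {
  assert_positive_scalar(n_genes, "n_genes")
  assert_positive_scalar(insertions_per_gene_mean, "insertions_per_gene_mean")
  assert_positive_scalar(doublings_per_cycle, "doublings_per_cycle")
  assert_positive_scalar(n_passages, "n_passages")
  assert_positive_scalar(n_replicates, "n_replicates")
  assert_positive_scalar(reads_per_sample, "reads_per_sample")
  if (intergenic_fraction < 0 || intergenic_fraction >= 1) {
    abort("`intergenic_fraction` must be in [0, 1)", class = "barseqfit_input_error")
  }
  if (abundance_lognormal_sigma < 0) {
    abort("`abundance_lognormal_sigma` must be nonnegative", class = "barseqfit_input_error")
  }

  unknown <- setdiff(names(class_proportions), PHENOTYPE_CLASSES)
  if (length(unknown) > 0) {
    abort(paste0("unknown phenotype class(es): ", paste(unknown, collapse = ", ")),
          class = "barseqfit_input_error")
  }
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must sum to 1", class = "barseqfit_input_error")
  }
  if (any(class_proportions < 0)) {
    abort("`class_proportions` must be nonnegative", class = "barseqfit_input_error")
  }

  if (length(recovery_schedule) != n_passages) {
    abort("`recovery_schedule` length must equal `n_passages`",
          class = "barseqfit_input_error")
  }

  default_capture <- list(
    neutral = wt_capture,
    nonadhesive_strong = 0.0,
    nonadhesive_mild = 0.3,
    hyperadhesive = 0.85,
    recovery = recovery_schedule,
    growth_defect = wt_capture
  )
  if (!is.null(class_capture)) {
    default_capture[names(class_capture)] <- class_capture
  }
  class_capture <- default_capture

  capture_values <- unlist(class_capture, use.names = FALSE)
  if (any(capture_values < 0 | capture_values > 1) ||
      wt_capture < 0 || wt_capture >= 1) {
    abort("all capture probabilities must lie in [0, 1]", class = "barseqfit_input_error")
  }

  penalty <- setNames(numeric(length(PHENOTYPE_CLASSES)), PHENOTYPE_CLASSES)
  penalty[names(growth_penalty)] <- growth_penalty

  structure(
    list(
      n_genes = as.integer(n_genes),
      insertions_per_gene_mean = insertions_per_gene_mean,
      intergenic_fraction = intergenic_fraction,
      class_proportions = class_proportions,
      wt_capture = wt_capture,
      class_capture = class_capture,
      growth_penalty = penalty,
      doublings_per_cycle = doublings_per_cycle,
      n_passages = as.integer(n_passages),
      n_replicates = as.integer(n_replicates),
      reads_per_sample = as.integer(reads_per_sample),
      abundance_lognormal_sigma = abundance_lognormal_sigma,
      overdispersion = overdispersion
    ),
    class = "sim_config"
  )
}

# Expand a class's capture entry to a full per-passage schedule.
capture_schedule_for <- function(config, class) {
  v <- config$class_capture[[class]]
  if (length(v) == 1) v <- rep(v, config$n_passages)
  if (length(v) != config$n_passages) {
    abort(sprintf("capture schedule for class '%s' has wrong length", class),
          class = "barseqfit_input_error")
  }
  v
}
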