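# Serial-passage dynamics and read sampling.
#
# One passage cycle: (optional) capture thinning by the cloth, regrowth to
# saturation, renormalization. Absolute cell numbers are never tracked;
# BarSeq observes composition only, so growth to saturation is pure
# renormalization and the doubling count matters only through per-strain
# growth penalties.
propagate_composition <- function(x0, dynamics, config, cheesecloth) {
  n_passages <- config$n_passages
  growth <- 2^(config$doublings_per_cycle * (1 + dynamics$penalty))
  out <- matrix(NA_real_, nrow = length(x0), ncol = n_passages)
  x <- x0 / sum(x0)
  for (t in seq_len(n_passages)) {
    if (cheesecloth) x <- x * (1 - dynamics$capture[, t])
    x <- x * growth
    x <- x / sum(x)
    out[, t] <- x
  }
  out
}

sample_id_for <- function(condition, passage, replicate) {
  sprintf("%s_p%d_%s", ifelse(condition == "cheesecloth", "cheese", "ctrl"),
          passage, LETTERS[replicate])
}

build_sample_sheet <- function(config) {
  grid <- tidyr::expand_grid(
    condition = c("control", "cheesecloth"),
    passage = seq_len(config$n_passages),
    replicate = seq_len(config$n_replicates)
  )
  tibble(
    sample_id = sample_id_for(grid$condition, grid$passage, grid$replicate),
    condition = grid$condition,
    passage = as.integer(grid$passage),
    replicate = LETTERS[grid$replicate],
    is_reference = grid$condition == "control" & grid$passage == 1L
  )
}

#' Simulate barcode count tables for a serial-passaging experiment
#'
#' Runs the forward model of pooled competition under cheesecloth selection.
#' Each replicate draws its own log-normal initial strain abundances (shared
#' between the two conditions of that replicate, as both wells are
#' inoculated from the same library aliquot).  Per passage cycle, the
#' planktonic fraction of strain *i* is thinned by `(1 - a_i(t))` in the
#' cheesecloth condition (`a_i(t) = 0` without cloth), multiplied by its
#' growth factor `2^(doublings * (1 + penalty_i))`, and renormalized.  A
#' multinomial read sample of depth `reads_per_sample` is drawn for every
#' (condition, passage, replicate); with `overdispersion > 0` the
#' composition is first jittered by a Dirichlet draw.  The sample sheet
#' marks the control passage-1 replicates as the reference group.
#'
#' @param pool A barcode pool from [build_pool()].
#' @param truth Truth labels from [assign_gene_classes()].
#' @param config A [sim_config()].
#' @param seed Integer seed; replicates use distinct derived seeds.
#' @return A list with `counts` (tibble, `barcode` + one column per sample),
#'   `sheet` (sample sheet tibble).
#' @examples
#' cfg <- sim_config(n_genes = 20, reads_per_sample = 2000)
#' pool <- build_pool(cfg, seed = 1)
#' truth <- assign_gene_classes(cfg, seed = 1)
#' sim <- simulate_counts(pool, truth, cfg, seed = 1)
#' dim(sim$counts)
#' @export
simulate_counts <- function(pool, truth, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(pool) == 0) abort("empty barcode pool", class = "barseqfit_input_error")
  if (config$reads_per_sample <= 0) {
    abort("`reads_per_sample` must be positive", class = "barseqfit_input_error")
  }
  dynamics <- strain_dynamics(pool, truth, config)
  sheet <- build_sample_sheet(config)

  n_strains <- nrow(pool)
  counts <- matrix(0L, nrow = n_strains, ncol = nrow(sheet),
                   dimnames = list(pool$barcode, sheet$sample_id))

  for (r in seq_len(config$n_replicates)) {
    withr::with_seed(derive_seed(seed, 100L + r), {
      x0 <- if (config$abundance_lognormal_sigma > 0) {
        rlnorm(n_strains, 0, config$abundance_lognormal_sigma)
      } else {
        rep(1, n_strains)
      }
      x0 <- x0 / sum(x0)
      for (cond in c("control", "cheesecloth")) {
        comp <- propagate_composition(x0, dynamics, config,
                                      cheesecloth = cond == "cheesecloth")
        for (t in seq_len(config$n_passages)) {
          p <- comp[, t]
          if (config$overdispersion > 0) {
            conc <- config$reads_per_sample / config$overdispersion
            g <- rgamma(n_strains, shape = p * conc, rate = 1)
            p <- g / sum(g)
          }
          sid <- sample_id_for(cond, t, r)
          counts[, sid] <- rmultinom(1, config$reads_per_sample, p)[, 1]
        }
      }
    })
  }

  list(counts = matrix_to_counts(counts), sheet = sheet)
}

#' Noise-free expected composition of the simulated experiment
#'
#' Iterates the deterministic passage recursion (no abundance draw, no read
#' sampling) from a perfectly even starting pool, and reports the expected
#' counts `frequency * reads_per_sample` for a single replicate of each
#' condition.  Used to verify the analytic enrichment properties of the
#' selection model independently of sampling noise.
#'
#' @inheritParams simulate_counts
#' @return A list with real-valued `counts` and a single-replicate `sheet`.
#' @export
simulate_expected <- function(pool, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(pool) == 0) abort("empty barcode pool", class = "barseqfit_input_error")
  dynamics <- strain_dynamics(pool, truth, config)
  cfg1 <- config
  cfg1$n_replicates <- 1L
  sheet <- build_sample_sheet(cfg1)

  n_strains <- nrow(pool)
  x0 <- rep(1 / n_strains, n_strains)
  counts <- matrix(NA_real_, nrow = n_strains, ncol = nrow(sheet),
                   dimnames = list(pool$barcode, sheet$sample_id))
  for (cond in c("control", "cheesecloth")) {
    comp <- propagate_composition(x0, dynamics, config,
                                  cheesecloth = cond == "cheesecloth")
    for (t in seq_len(config$n_passages)) {
      counts[, sample_id_for(cond, t, 1L)] <- comp[, t] * config$reads_per_sample
    }
  }
  list(counts = matrix_to_counts(counts), sheet = sheet)
}
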