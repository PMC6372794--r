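test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_genes = 0), class = "barseqfit_input_error")
  expect_error(sim_config(intergenic_fraction = 1), class = "barseqfit_input_error")
  expect_error(
    sim_config(class_proportions = c(neutral = 0.7, hyperadhesive = 0.2)),
    class = "barseqfit_input_error"
  )
  expect_error(
    sim_config(class_proportions = c(neutral = 0.5, unknown_class = 0.5)),
    class = "barseqfit_input_error"
  )
  expect_error(sim_config(class_capture = list(hyperadhesive = 1.2)),
               class = "barseqfit_input_error")
  expect_error(sim_config(recovery_schedule = c(0.9, 0.5)),
               class = "barseqfit_input_error")
})

test_that("pool construction honors its postconditions", {
  cfg <- sim_config(n_genes = 2, insertions_per_gene_mean = 1,
                    intergenic_fraction = 0)
  pool <- build_pool(cfg, seed = 7)
  expect_equal(dplyr::n_distinct(pool$locus), 2)
  expect_false(any(pool$locus == "intergenic"))
  expect_false(anyDuplicated(pool$barcode) > 0)
  expect_true(all(pool$orf_fraction > 0 & pool$orf_fraction < 1))
  expect_true(all(nchar(pool$barcode) == 20))

  # determinism: identical seed, identical pool
  expect_identical(pool, build_pool(cfg, seed = 7))
  expect_false(identical(pool, build_pool(cfg, seed = 8)))
})

test_that("strains per gene follow the zero-truncated Poisson mean", {
  cfg <- sim_config(n_genes = 1000, insertions_per_gene_mean = 3,
                    intergenic_fraction = 0)
  pool <- build_pool(cfg, seed = 11)
  per_gene <- table(pool$locus)
  mom <- ztpois_moments(3)
  # closed form agrees with pmf enumeration
  expect_equal(mom$mean, 3 / (1 - exp(-3)), tolerance = 1e-12)
  se <- sqrt(mom$var / 1000)
  expect_lt(abs(mean(per_gene) - mom$mean), 3 * se)
  expect_true(all(per_gene >= 1))
})

test_that("intergenic strains make up the configured fraction", {
  cfg <- sim_config(n_genes = 500, intergenic_fraction = 0.15)
  pool <- build_pool(cfg, seed = 3)
  expect_equal(mean(pool$locus == "intergenic"), 0.15, tolerance = 0.01)
  expect_true(all(is.na(pool$orf_fraction[pool$locus == "intergenic"])))
})

test_that("class assignment follows the configured proportions", {
  cfg <- sim_config(n_genes = 10, class_proportions = c(neutral = 1.0))
  truth <- assign_gene_classes(cfg, seed = 5)
  expect_true(all(truth$class == "neutral"))

  cfg2 <- sim_config(n_genes = 1000,
                     class_proportions = c(neutral = 0.5, hyperadhesive = 0.5))
  truth2 <- assign_gene_classes(cfg2, seed = 5)
  n_hyper <- sum(truth2$class == "hyperadhesive")
  # binomial 99% interval around 500
  expect_true(abs(n_hyper - 500) < qnorm(0.995) * sqrt(1000 * 0.25))

  # recovery genes carry the configured schedule verbatim
  cfg3 <- sim_config(n_genes = 200,
                     class_proportions = c(neutral = 0.5, recovery = 0.5))
  truth3 <- assign_gene_classes(cfg3, seed = 5)
  rec <- truth3[truth3$class == "recovery", ][1, ]
  expect_equal(
    unlist(rec[sprintf("capture_p%d", 1:5)], use.names = FALSE),
    c(0.9, 0.9, 0.7, 0.5, 0.3)
  )
})

test_that("control-condition composition is preserved for neutral pools", {
  cfg <- sim_config(n_genes = 30, class_proportions = c(neutral = 1.0),
                    intergenic_fraction = 0, reads_per_sample = 50000)
  pool <- build_pool(cfg, seed = 2)
  truth <- assign_gene_classes(cfg, seed = 2)

  # deterministic recursion: exact preservation
  ex <- simulate_expected(pool, truth, cfg)
  m <- as.matrix(ex$counts[-1])
  ctrl <- m[, grep("^ctrl", colnames(m))]
  expect_equal(ctrl, ctrl[, c(1, 1, 1, 1, 1)], ignore_attr = TRUE,
               tolerance = 1e-12)

  # with sampling: observed per-strain frequencies near initial composition
  sim <- simulate_counts(pool, truth, cfg, seed = 2)
  ms <- as.matrix(sim$counts[-1])
  p1 <- ms[, "ctrl_p1_A"] / sum(ms[, "ctrl_p1_A"])
  p5 <- ms[, "ctrl_p5_A"] / sum(ms[, "ctrl_p5_A"])
  # both draws estimate the same composition: 99% multinomial band on diff
  se <- sqrt(p1 * (1 - p1) * 2 / cfg$reads_per_sample)
  expect_true(mean(abs(p5 - p1) < qnorm(0.995) * se + 1e-6) > 0.95)
})

test_that("selection separates planted classes monotonically", {
  cfg <- sim_config(n_genes = 40, intergenic_fraction = 0,
                    class_proportions = c(neutral = 0.8,
                                          nonadhesive_strong = 0.1,
                                          hyperadhesive = 0.1))
  pool <- build_pool(cfg, seed = 9)
  truth <- assign_gene_classes(cfg, seed = 9)
  ex <- simulate_expected(pool, truth, cfg)
  m <- as.matrix(ex$counts[-1])
  rownames(m) <- ex$counts$barcode
  cheese <- m[, grep("^cheese", colnames(m))]
  strong_bc <- pool$barcode[pool$locus %in% truth$locus[truth$class == "nonadhesive_strong"]][1]
  hyper_bc <- pool$barcode[pool$locus %in% truth$locus[truth$class == "hyperadhesive"]][1]
  neutral_bc <- pool$barcode[pool$locus %in% truth$locus[truth$class == "neutral"]][1]
  ratio_strong <- cheese[strong_bc, ] / cheese[neutral_bc, ]
  ratio_hyper <- cheese[hyper_bc, ] / cheese[neutral_bc, ]
  expect_true(all(diff(ratio_strong) > 0))
  expect_true(all(diff(ratio_hyper) < 0))
  # per-passage gain of the fully nonadhesive strain: 1/(1 - 0.6) = 2.5
  expect_equal(unname(ratio_strong[-1] / ratio_strong[-5]), rep(2.5, 4),
               tolerance = 1e-9)
})

test_that("count simulation is deterministic with per-replicate streams", {
  cfg <- small_sim_config()
  pool <- build_pool(cfg, seed = 4)
  truth <- assign_gene_classes(cfg, seed = 4)
  sim1 <- simulate_counts(pool, truth, cfg, seed = 21)
  sim2 <- simulate_counts(pool, truth, cfg, seed = 21)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$sheet, sim2$sheet)
  sim3 <- simulate_counts(pool, truth, cfg, seed = 22)
  expect_false(identical(sim1$counts, sim3$counts))
  # replicates are distinct draws, not copies
  m <- as.matrix(sim1$counts[-1])
  expect_false(identical(m[, "ctrl_p1_A"], m[, "ctrl_p1_B"]))
  # reference group is the three control passage-1 samples
  expect_equal(sim1$sheet$sample_id[sim1$sheet$is_reference],
               c("ctrl_p1_A", "ctrl_p1_B", "ctrl_p1_C"))
})

test_that("emitted reads embed each barcode exactly count times", {
  fl <- flank_spec()
  pool <- tibble::tibble(
    barcode = c(strrep("A", 20), strrep("C", 20)),
    scaffold = "chr1", strand = "+", position = c(1L, 2L),
    locus = c("gene_01", "gene_02"), orf_fraction = c(0.5, 0.5)
  )
  counts <- tibble::tibble(barcode = pool$barcode, s1 = c(3L, 0L))
  dir <- withr::local_tempdir()
  files <- emit_reads(counts, pool, fl, dir, seed = 1)
  lines <- readLines(files$path[1])
  expect_equal(length(lines), 12)
  seqs <- lines[seq(2, 12, by = 4)]
  expect_true(all(grepl(paste0(fl$pre, pool$barcode[1], fl$post), seqs,
                        fixed = TRUE)))
  # deterministic given seed
  files2 <- emit_reads(counts, pool, fl, withr::local_tempdir(), seed = 1)
  expect_identical(readLines(files2$path[1]), lines)
})

test_that("substitution errors break exact extraction at the binomial rate", {
  fl <- flank_spec()  # 18 + 18 nt flanks
  n <- 20000
  withr::with_seed(31, {
    bc <- stringi::stri_rand_strings(1, 20, "[ACGT]")
  })
  pool <- tibble::tibble(barcode = bc, scaffold = "chr1", strand = "+",
                         position = 1L, locus = "gene_01", orf_fraction = 0.5)
  counts <- tibble::tibble(barcode = bc, s1 = as.integer(n))
  dir <- withr::local_tempdir()
  files <- emit_reads(counts, pool, fl, dir, seed = 2, error_rate = 0.01)
  res <- count_sample(files$path[1], fl)
  # extraction fails when a substitution lands in either flank (36 nt);
  # errors in the barcode itself still extract (as a different barcode)
  p_fail <- 1 - 0.99^36
  frac_fail <- 1 - res$stats$reads_with_barcode / res$stats$total_reads
  se <- sqrt(p_fail * (1 - p_fail) / n)
  expect_lt(abs(frac_fail - p_fail), 4 * se)
})
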