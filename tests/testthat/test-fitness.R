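# Direct formula checks for strain fitness, on a 100-barcode table built to
# hit the worked values exactly.
test_that("strain fitness reproduces closed-form log ratios", {
  b <- 100
  barcodes <- sprintf("bc%03d", seq_len(b))
  sheet <- make_sheet(n_ref = 1, cells = list(c("cheesecloth", 1)))
  # reference: barcode 1 has 10 reads, the rest split 990 evenly; sample:
  # barcode 1 has 40, the rest split 960 evenly; depths both 1000
  ref <- c(10, rep(10, b - 1))
  smp <- c(40, rep(960 / (b - 1), b - 1))
  counts <- tibble::tibble(barcode = barcodes, ctrl_p1_A = ref,
                           cheese_p1_A = smp)

  # ps = 0, equal depths: f = log2(40/10) = 2 exactly
  st0 <- strain_fitness(counts, sheet,
                        fitness_params(pseudocount = 0, min_reference_count = 0))
  expect_equal(st0$fitness[st0$barcode == "bc001"], 2.0, tolerance = 1e-12)

  # ps = 1, D = 1000, B = 100: f = log2(41/1100) - log2(11/1100) = log2(41/11)
  st1 <- strain_fitness(counts, sheet,
                        fitness_params(pseudocount = 1, min_reference_count = 0))
  expect_equal(st1$fitness[st1$barcode == "bc001"], log2(41 / 11),
               tolerance = 1e-12)

  # identity: a sample equal to the pooled reference has f = 0 for every ps
  counts_id <- tibble::tibble(barcode = barcodes, ctrl_p1_A = ref,
                              cheese_p1_A = ref)
  for (ps in c(0, 0.5, 1, 5)) {
    st <- strain_fitness(counts_id, sheet,
                         fitness_params(pseudocount = ps, min_reference_count = 0))
    expect_equal(st$fitness, rep(0, b), tolerance = 1e-12)
  }
})

test_that("reference-count threshold controls usability", {
  sheet <- make_sheet(n_ref = 2, cells = list(c("cheesecloth", 1)))
  counts <- tibble::tibble(
    barcode = c("bcA", "bcB", "bcC"),
    ctrl_p1_A = c(1L, 5L, 0L), ctrl_p1_B = c(1L, 5L, 1L),
    cheese_p1_A = c(4L, 4L, 4L)
  )
  st <- strain_fitness(counts, sheet, fitness_params(min_reference_count = 3))
  expect_equal(st$usable, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(st$fitness[!st$usable])))
  expect_false(anyNA(st$fitness[st$usable]))

  # errors: no reference samples; zero-depth sample
  no_ref <- sheet |> dplyr::mutate(is_reference = FALSE, condition = "cheesecloth",
                                   sample_id = sub("ctrl", "cheese", sample_id),
                                   passage = c(2L, 2L, 1L),
                                   replicate = c("A", "B", "A"))
  expect_error(strain_fitness(counts, no_ref, fitness_params()),
               class = "barseqfit_input_error")
  zero <- counts |> dplyr::mutate(cheese_p1_A = 0L)
  expect_error(strain_fitness(zero, sheet, fitness_params()),
               "zero-depth", class = "barseqfit_input_error")
})

test_that("fitness is strictly monotone in the sample count", {
  sheet <- make_sheet(n_ref = 1, cells = list(c("cheesecloth", 1)))
  f_at <- function(n) {
    counts <- tibble::tibble(barcode = c("bcA", "bcB"),
                             ctrl_p1_A = c(10, 90),
                             cheese_p1_A = c(n, 100 - n))
    st <- strain_fitness(counts, sheet, fitness_params(min_reference_count = 0))
    st$fitness[st$barcode == "bcA"]
  }
  vals <- vapply(seq(5, 60, by = 5), f_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("gene fitness applies the central window and weighted average", {
  sheet <- make_sheet(n_ref = 1, cells = list(c("cheesecloth", 1)))
  pool <- tibble::tibble(
    barcode = c("bcA", "bcB", "bcC", "bcD", "bcE"),
    scaffold = "chr1", strand = "+", position = 1:5,
    locus = c("gene_01", "gene_01", "gene_02", "gene_02", "gene_02"),
    orf_fraction = c(0.05, 0.50, 0.10, 0.90, 0.95)
  )
  counts <- tibble::tibble(
    barcode = pool$barcode,
    ctrl_p1_A = c(10, 10, 20, 20, 20),
    cheese_p1_A = c(10240, 10, 40, 40, 640)
  )
  params <- fitness_params(pseudocount = 0, min_reference_count = 0)
  st <- strain_fitness(counts, sheet, params)
  gf <- gene_fitness(st, counts, pool, sheet, params)

  # gene_01: the orf_fraction 0.05 strain (huge f) is excluded; gene fitness
  # equals the lone central strain's fitness for any weighting
  f_central <- st$fitness[st$barcode == "bcB"]
  expect_equal(gf$fitness[gf$locus == "gene_01"], f_central, tolerance = 1e-12)
  expect_equal(gf$n_strains_used[gf$locus == "gene_01"], 1L)
  for (w in c("reference_count", "uniform")) {
    gfw <- gene_fitness(st, counts, pool, sheet,
                        fitness_params(pseudocount = 0, min_reference_count = 0,
                                       weighting = w))
    expect_equal(gfw$fitness[gfw$locus == "gene_01"], f_central,
                 tolerance = 1e-12)
  }

  # gene_02: window endpoints 0.10 and 0.90 are inclusive, 0.95 is out
  expect_equal(gf$n_strains_used[gf$locus == "gene_02"], 2L)
  # equal counts means equal weights: plain mean of the two strain values
  f_bc <- st$fitness[st$barcode %in% c("bcC", "bcD")]
  expect_equal(gf$fitness[gf$locus == "gene_02"], mean(f_bc), tolerance = 1e-12)

  # weighted mean stays within the strain fitness range (all weightings)
  fix <- random_fitness_fixture(7, n_bc = 12, n_genes = 3, min_count = 1)
  stf <- strain_fitness(fix$counts, fix$sheet, params)
  for (w in c("precision", "reference_count", "uniform")) {
    gfw <- gene_fitness(stf, fix$counts, fix$pool, fix$sheet,
                        fitness_params(pseudocount = 0.5, weighting = w))
    joined <- dplyr::inner_join(
      stf |> dplyr::inner_join(fix$pool[c("barcode", "locus", "orf_fraction")],
                               by = "barcode") |>
        dplyr::filter(usable, locus != "intergenic",
                      orf_fraction >= 0.1, orf_fraction <= 0.9) |>
        dplyr::summarise(lo = min(fitness), hi = max(fitness),
                         .by = c(locus, sample)),
      gfw, by = c("locus", "sample")
    )
    expect_true(all(joined$fitness >= joined$lo - 1e-12 &
                      joined$fitness <= joined$hi + 1e-12))
  }
})

test_that("genes with no eligible strain carry no value", {
  sheet <- make_sheet(n_ref = 1, cells = list(c("cheesecloth", 1)))
  pool <- tibble::tibble(
    barcode = c("bcA", "bcB"), scaffold = "chr1", strand = "+", position = 1:2,
    locus = c("gene_01", "gene_02"), orf_fraction = c(0.05, 0.5)
  )
  counts <- tibble::tibble(barcode = pool$barcode,
                           ctrl_p1_A = c(50, 50), cheese_p1_A = c(50, 50))
  params <- fitness_params()
  gf <- gene_fitness(strain_fitness(counts, sheet, params), counts, pool,
                     sheet, params)
  expect_false("gene_01" %in% gf$locus)  # only strain is outside the window
  expect_true("gene_02" %in% gf$locus)

  # pool barcode missing from the strain table is an error
  st_partial <- strain_fitness(counts, sheet, params) |>
    dplyr::filter(barcode != "bcB")
  expect_error(gene_fitness(st_partial, counts, pool, sheet, params),
               "bcB", class = "barseqfit_input_error")
})

test_that("median centering shifts, is idempotent, and 'none' is identity", {
  genes <- tibble::tibble(
    locus = rep(c("g1", "g2", "g3"), 2),
    sample = rep(c("s1", "s2"), each = 3),
    fitness = c(1, 2, 9, -1, 0, 1),
    n_strains_used = 1L
  )
  centered <- center_fitness(genes, "median")
  expect_equal(centered$fitness[centered$sample == "s1"], c(-1, 0, 7))
  expect_equal(centered$fitness[centered$sample == "s2"], c(-1, 0, 1))
  expect_identical(center_fitness(genes, "none"), genes)
  expect_equal(center_fitness(centered, "median"), centered)
  expect_error(center_fitness(genes[1:2, ], "median"),
               class = "barseqfit_input_error")
})
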