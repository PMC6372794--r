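# Independent oracles: literal, loop-based re-evaluations of the defining
# formulas. They intentionally share no code path with the package.

oracle_strain_fitness <- function(m, ref_ids, ps, min_ref) {
  b <- nrow(m)
  n0 <- apply(m[, ref_ids, drop = FALSE], 1, sum)
  d0 <- sum(m[, ref_ids])
  nonref <- setdiff(colnames(m), ref_ids)
  rows <- list()
  for (s in nonref) {
    ds <- sum(m[, s])
    for (bc in rownames(m)) {
      usable <- n0[bc] >= min_ref
      f <- if (usable) {
        log2((m[bc, s] + ps) / (ds + ps * b)) -
          log2((n0[bc] + ps) / (d0 + ps * b))
      } else {
        NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        barcode = bc, sample = s, fitness = f, usable = usable,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

oracle_gene_fitness <- function(m, ref_ids, pool, ps, min_ref, window, weighting) {
  sf <- oracle_strain_fitness(m, ref_ids, ps, min_ref)
  n0 <- apply(m[, ref_ids, drop = FALSE], 1, sum)
  nonref <- setdiff(colnames(m), ref_ids)
  rows <- list()
  for (g in unique(pool$locus[pool$locus != "intergenic"])) {
    bcs <- pool$barcode[pool$locus == g]
    for (s in nonref) {
      num <- 0
      den <- 0
      used <- 0
      for (bc in bcs) {
        of <- pool$orf_fraction[pool$barcode == bc]
        if (is.na(of) || of < window[1] || of > window[2]) next
        if (n0[bc] < min_ref) next
        f <- sf$fitness[sf$barcode == bc & sf$sample == s]
        w <- switch(weighting,
          precision = 1 / (1 / (m[bc, s] + ps) + 1 / (n0[bc] + ps)),
          reference_count = n0[bc] + ps,
          uniform = 1
        )
        num <- num + w * f
        den <- den + w
        used <- used + 1
      }
      if (used > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          locus = g, sample = s, fitness = num / den, n_strains_used = used,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

# Exhaustive placement search for barcode extraction (leftmost valid
# placement; ambiguous barcode at a valid placement is a definitive miss).
brute_force_extract <- function(read, pre, post, bl, mm) {
  hm <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(utf8ToInt(a) != utf8ToInt(b))
  }
  lp <- nchar(pre)
  lq <- nchar(post)
  last <- nchar(read) - lp - bl - lq + 1
  if (last < 1) return(NA_character_)
  for (i in seq_len(last)) {
    if (hm(substr(read, i, i + lp - 1), pre) > mm) next
    pstart <- i + lp + bl
    if (hm(substr(read, pstart, pstart + lq - 1), post) > mm) next
    bc <- substr(read, i + lp, i + lp + bl - 1)
    if (grepl("^[ACGT]+$", bc)) return(bc)
    return(NA_character_)
  }
  NA_character_
}

# Zero-truncated Poisson moments by direct enumeration of the truncated pmf.
ztpois_moments <- function(lambda, kmax = 60) {
  k <- 1:kmax
  p <- stats::dpois(k, lambda) / (1 - exp(-lambda))
  list(mean = sum(k * p), var = sum(k^2 * p) - sum(k * p)^2)
}
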