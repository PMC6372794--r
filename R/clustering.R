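# Clustering of temporal profiles, cofitness, and archetype labeling.

profiles_to_matrix <- function(norm) {
  wide <- norm |>
    arrange(.data$locus, .data$passage) |>
    tidyr::pivot_wider(names_from = "passage", values_from = "g",
                       names_prefix = "p")
  if (anyNA(wide)) {
    abort("normalized profiles of unequal length", class = "barseqfit_input_error")
  }
  m <- as.matrix(wide[setdiff(names(wide), "locus")])
  rownames(m) <- wide$locus
  # canonical row order makes downstream clustering independent of input order
  m[order(rownames(m)), , drop = FALSE]
}

#' Pairwise distances between temporal fitness profiles
#'
#' Euclidean is the L2 distance between `g` vectors; correlation is
#' `1 - Pearson(g_a, g_b)`.  Zero-variance profiles have no defined
#' correlation; they are assigned distance 1 to everything (0 on the
#' diagonal) and flagged in the `"zero_variance"` attribute.
#'
#' @param norm Normalized profile tibble from [condition_normalize()].
#' @param metric `"euclidean"` (default) or `"correlation"`.
#' @return Symmetric zero-diagonal distance matrix with locus dimnames.
#' @export
profile_distance <- function(norm, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  m <- profiles_to_matrix(norm)
  if (nrow(m) < 2) {
    abort("at least 2 genes are required", class = "barseqfit_input_error")
  }
  if (metric == "euclidean") {
    d <- as.matrix(dist(m, method = "euclidean"))
    attr(d, "zero_variance") <- character(0)
  } else {
    sds <- apply(m, 1, sd)
    flagged <- rownames(m)[sds == 0]
    d <- matrix(1, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
    ok <- sds > 0
    if (sum(ok) >= 2) {
      d[ok, ok] <- 1 - cor(t(m[ok, , drop = FALSE]))
    }
    diag(d) <- 0
    attr(d, "zero_variance") <- flagged
  }
  d
}

#' Agglomerative clustering of profile distances
#'
#' Standard hierarchical clustering of a profile distance matrix, cut to
#' exactly `k` flat clusters.  Rows are taken in canonical (locus-sorted)
#' order and cluster ids are relabeled 1..k by first appearance, so the
#' result is a deterministic function of the distances alone.
#'
#' @param distances Distance matrix from [profile_distance()].
#' @param linkage `"ward"` (Ward's criterion on squared distances,
#'   default), `"average"`, or `"complete"`.
#' @param k Number of flat clusters.
#' @return Object of class `barseq_clust`: list with `assignment`
#'   (tibble `locus`, `cluster`), `tree` (the `hclust` object), `merges`
#'   (tibble `left`, `right`, `height`), `k`, `linkage`.
#' @export
hierarchical_cluster <- function(distances, linkage = c("ward", "average", "complete"),
                                 k) {
  linkage <- match.arg(linkage)
  n <- nrow(distances)
  if (k > n) abort("`k` cannot exceed the number of genes",
                   class = "barseqfit_input_error")
  if (k < 1) abort("`k` must be >= 1", class = "barseqfit_input_error")
  ord <- order(rownames(distances))
  d <- distances[ord, ord]
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  tree <- hclust(as.dist(d), method = method)
  raw <- cutree(tree, k = k)
  # relabel by first appearance in locus order
  relabel <- match(raw, unique(raw))
  assignment <- tibble(locus = names(raw), cluster = as.integer(relabel))
  merges <- tibble(left = tree$merge[, 1], right = tree$merge[, 2],
                   height = tree$height)
  structure(
    list(assignment = assignment, tree = tree, merges = merges,
         k = as.integer(k), linkage = linkage),
    class = "barseq_clust"
  )
}

#' @export
print.barseq_clust <- function(x, ...) {
  cat(sprintf("Hierarchical clustering of %d temporal profiles (%s linkage, k = %d)\n",
              nrow(x$assignment), x$linkage, x$k))
  print(dplyr::count(x$assignment, .data$cluster))
  invisible(x)
}

#' @export
tidy.barseq_clust <- function(x, ...) {
  x$assignment
}

#' @export
glance.barseq_clust <- function(x, ...) {
  tibble(n_genes = nrow(x$assignment), k = x$k, linkage = x$linkage,
         max_height = max(x$tree$height))
}

#' Cofitness: correlation between genes' temporal profiles
#'
#' Pearson correlation of normalized profile vectors; genes whose profiles
#' move together under selection are candidates for shared function.
#' Zero-variance profiles get correlation 0 (diagonal 1) and are flagged in
#' the `"zero_variance"` attribute.
#'
#' @param norm Normalized profile tibble.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
cofitness_matrix <- function(norm) {
  m <- profiles_to_matrix(norm)
  if (ncol(m) < 2) {
    abort("cofitness needs at least 2 passages per profile",
          class = "barseqfit_input_error")
  }
  sds <- apply(m, 1, sd)
  flagged <- rownames(m)[sds == 0]
  r <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  ok <- sds > 0
  if (sum(ok) >= 2) r[ok, ok] <- cor(t(m[ok, , drop = FALSE]))
  diag(r) <- 1
  attr(r, "zero_variance") <- flagged
  r
}

#' Highest-cofitness partners of a gene
#'
#' @param gene Query locus.
#' @param matrix Cofitness matrix from [cofitness_matrix()].
#' @param n Number of partners to return.
#' @return Tibble `locus`, `cofitness`, ordered by descending correlation
#'   (ties broken by locus).  Empty (with a warning) when the query profile
#'   had zero variance.
#' @export
top_cofit_partners <- function(gene, matrix, n) {
  if (!gene %in% rownames(matrix)) {
    abort(sprintf("unknown gene '%s'", gene), class = "barseqfit_input_error")
  }
  flagged <- attr(matrix, "zero_variance") %||% character(0)
  if (gene %in% flagged) {
    warn(sprintf("gene '%s' has a zero-variance profile; no cofitness defined", gene))
    return(tibble(locus = character(0), cofitness = numeric(0)))
  }
  r <- matrix[gene, setdiff(colnames(matrix), gene)]
  out <- tibble(locus = names(r), cofitness = unname(r)) |>
    arrange(desc(.data$cofitness), .data$locus)
  head(out, min(n, nrow(out)))
}

#' Thresholds for archetype labeling of temporal profiles
#'
#' Quantifies the qualitative temporal classes seen in adhesion selections
#' so cluster interpretation is reproducible rather than manual:
#' `theta_strong` is the final-passage enrichment that marks a strong
#' adhesion-loss (biosynthesis-like) profile; `theta_mild` the milder
#' (modification-like) enrichment; `theta_neg` the depth of early depletion;
#' `floor` the lowest final value still consistent with recovery or with a
#' nonnegative trajectory; `rho_recovery` the minimum climb from the
#' trajectory minimum to the final passage for a recovery call.
#'
#' @param theta_strong Default 2.0 (log2 units).
#' @param theta_mild Default 0.5.
#' @param theta_neg Default -1.0.
#' @param floor Default -0.5.
#' @param rho_recovery Default 1.5.
#' @return An `archetype_thresholds` list.
#' @export
archetype_thresholds <- function(theta_strong = 2.0, theta_mild = 0.5,
                                 theta_neg = -1.0, floor = -0.5,
                                 rho_recovery = 1.5) {
  if (!(theta_strong > theta_mild && theta_mild > 0 && 0 > theta_neg)) {
    abort("thresholds must satisfy theta_strong > theta_mild > 0 > theta_neg",
          class = "barseqfit_input_error")
  }
  structure(
    list(theta_strong = theta_strong, theta_mild = theta_mild,
         theta_neg = theta_neg, floor = floor, rho_recovery = rho_recovery),
    class = "archetype_thresholds"
  )
}

label_one_archetype <- function(g, th) {
  gmin <- min(g)
  gend <- g[length(g)]
  if (min(g[1], g[2]) <= th$theta_neg &&
      gend - gmin >= th$rho_recovery &&
      gend >= th$floor) {
    return("recovery")
  }
  if (gmin <= th$theta_neg && gend <= th$floor) return("hyperadhesive")
  if (gend >= th$theta_strong && gmin >= th$floor) return("biosynthesis")
  if (gend >= th$theta_mild && gend < th$theta_strong && gmin >= th$floor) {
    return("modification")
  }
  "unclassified"
}

#' Rule-based archetype labels for temporal profiles
#'
#' Applies, in order, explicit rules for the four temporal shapes of
#' adhesion phenotypes: early depletion followed by a climb back toward
#' neutral (`recovery`), sustained depletion (`hyperadhesive`), strong
#' monotone-style enrichment (`biosynthesis`), and modest enrichment
#' (`modification`); profiles matching none are `unclassified`.  Recovery
#' is tested before hyperadhesive so early-negative-then-rising profiles
#' are not swallowed by the depletion rule.
#'
#' @param norm Normalized profile tibble.
#' @param thresholds An [archetype_thresholds()].
#' @return Tibble `locus`, `archetype`.
#' @export
label_archetypes <- function(norm, thresholds = archetype_thresholds()) {
  stopifnot(inherits(thresholds, "archetype_thresholds"))
  m <- profiles_to_matrix(norm)
  tibble(
    locus = rownames(m),
    archetype = apply(m, 1, label_one_archetype, th = thresholds)
  )
}
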