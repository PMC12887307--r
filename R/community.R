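#' Construct an ASV count table
#'
#' Container for an ASV (amplicon sequence variant) count matrix with
#' taxonomy lineages and per-sample metadata. Counts are stored with ASVs as
#' rows and samples as columns, matching the interchange TSV layout; vegan
#' calls transpose internally.
#'
#' @param counts non-negative integer matrix, ASVs x samples, with unique
#'   row (ASV id) and column (sample) names.
#' @param taxonomy character vector of semicolon-delimited rank lineages,
#'   one per ASV; the sixth field is the genus.
#' @param metadata optional data frame with a `sample` column (and typically
#'   a `time_point`), one row per sample.
#' @return object of class `ces_asv_table`.
#' @export
asv_table <- function(counts, taxonomy, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stopf("counts must have unique ASV row names")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stopf("counts must have unique sample column names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  if (length(taxonomy) != nrow(counts)) {
    stopf("need one taxonomy string per ASV")
  }
  if (!is.null(metadata)) {
    stopifnot(is.data.frame(metadata), "sample" %in% names(metadata))
    metadata <- metadata[match(colnames(counts), metadata$sample), , drop = FALSE]
  }
  structure(
    list(counts = counts, taxonomy = as.character(taxonomy),
         metadata = metadata),
    class = "ces_asv_table"
  )
}

#' @export
print.ces_asv_table <- function(x, ...) {
  cat(sprintf("<ces_asv_table> %d ASVs x %d samples, %d reads total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Remove low-count ASVs
#'
#' Drops ASVs whose total read count across all samples falls below
#' `min_total_reads` (default 2, i.e. dataset-wide singleton removal, the
#' usual artifact filter). With `per_sample = TRUE` an ASV is instead kept
#' if any single sample reaches the threshold.
#'
#' @param table a `ces_asv_table`.
#' @param min_total_reads minimum read count for retention.
#' @param per_sample apply the threshold per sample instead of to totals.
#' @return the filtered `ces_asv_table` (samples unchanged).
#' @export
filter_asv_table <- function(table, min_total_reads = 2, per_sample = FALSE) {
  stopifnot(inherits(table, "ces_asv_table"))
  keep <- if (per_sample) {
    apply(table$counts, 1, max) >= min_total_reads
  } else {
    rowSums(table$counts) >= min_total_reads
  }
  if (!any(keep)) stopf("filter removed every ASV")
  asv_table(table$counts[keep, , drop = FALSE], table$taxonomy[keep],
            table$metadata)
}

# Genus = 6th semicolon-delimited rank; tolerant of "g__" prefixes and
# missing fields.
genus_from_taxonomy <- function(taxonomy) {
  vapply(strsplit(taxonomy, ";"), function(parts) {
    if (length(parts) < 6L) return("unclassified_genus")
    g <- trimws(parts[[6]])
    g <- sub("^[a-z]__", "", g)
    if (!nzchar(g)) "unclassified_genus" else g
  }, "")
}

#' Genus-level relative abundance of the most abundant genera
#'
#' Sums ASV counts by genus, converts to per-sample relative abundances,
#' ranks genera by mean relative abundance across samples, and returns the
#' top `n` with everything else aggregated as `"other"`.
#'
#' @param table a `ces_asv_table`.
#' @param n number of genera to keep.
#' @return numeric matrix, genera x samples, columns summing to 1.
#' @export
genus_top_abundance <- function(table, n = 20) {
  stopifnot(inherits(table, "ces_asv_table"))
  genus <- genus_from_taxonomy(table$taxonomy)
  agg <- rowsum(table$counts, group = genus)
  rel <- sweep(agg, 2, colSums(agg), "/")
  ord <- order(rowMeans(rel), decreasing = TRUE)
  rel <- rel[ord, , drop = FALSE]
  if (nrow(rel) > n) {
    top <- rel[seq_len(n), , drop = FALSE]
    other <- colSums(rel[-seq_len(n), , drop = FALSE])
    rel <- rbind(top, other = other)
  }
  rel
}

#' Shannon diversity index (nats)
#'
#' \eqn{H = -\sum p_i \ln p_i} over the relative abundances of one sample's
#' counts. Used both for community alpha diversity and, via
#' [chemodiversity()], for DOM intensity profiles.
#'
#' @param x numeric vector with at least one positive entry.
#' @return Shannon index in nats.
#' @examples
#' shannon_index(c(1, 1, 2)) # 1.039721
#' @export
shannon_index <- function(x) shannon_entropy(x)

#' Per-sample Shannon diversity of an ASV table
#' @param table a `ces_asv_table`.
#' @return named numeric vector, one H per sample.
#' @export
sample_shannon <- function(table) {
  stopifnot(inherits(table, "ces_asv_table"))
  apply(table$counts, 2, shannon_entropy)
}

#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} over ASV counts.
#'
#' @param table a `ces_asv_table` or a samples-in-rows numeric matrix.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "ces_asv_table")) t(table$counts) else as.matrix(table)
  if (nrow(m) < 2L) stopf("need at least two samples")
  if (any(rowSums(m) == 0)) {
    stopf("sample(s) with zero total counts: %s",
          paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double-centering
#' of \eqn{-D^2/2}, eigendecomposition, and coordinates scaled by the square
#' roots of the positive eigenvalues. Negative eigenvalues (possible for
#' non-Euclidean dissimilarities such as Bray-Curtis) are reported but not
#' embedded.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities, >= 3 samples.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   descending) and `proportion_explained` (relative to the positive part).
#' @export
pcoa_ordination <- function(d) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < 3L) stopf("PCoA requires at least 3 samples")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(abs(eig)) * 1e-10)
  coords <- fit$points
  if (length(pos) == 0L) {
    coords <- matrix(0, n, 1, dimnames = list(labels(d), "Axis1"))
    prop <- 1
  } else {
    coords <- coords[, seq_along(pos), drop = FALSE]
    colnames(coords) <- paste0("Axis", seq_along(pos))
    prop <- eig[pos] / sum(eig[pos])
  }
  list(coordinates = coords, eigenvalues = eig, proportion_explained = prop)
}

#' PERMANOVA: permutational multivariate ANOVA on a distance matrix
#'
#' One-factor PERMANOVA in Anderson's formulation (via [vegan::adonis2()]):
#' pseudo-F from between/within sums of squared dissimilarities, with a
#' seeded free permutation of sample labels and the
#' \eqn{p = (\#\{F^* \ge F\} + 1)/(n_{perm} + 1)} convention.
#'
#' @param d a `dist` of pairwise dissimilarities.
#' @param groups factor of group labels, one per sample, >= 2 groups.
#' @param permutations number of label permutations (or a permutation matrix
#'   for exact enumeration).
#' @param seed RNG seed for the permutations (NULL = current stream).
#' @return list with `pseudo_f`, `r_squared`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
permanova <- function(d, groups, permutations = 999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) stopf("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2L) stopf("PERMANOVA requires >= 2 groups")
  dat <- data.frame(groups = groups)
  fit <- with_seed(seed, vegan::adonis2(d ~ groups, data = dat,
                                        permutations = permutations))
  list(
    pseudo_f = fit$F[1],
    r_squared = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_permutations = if (is.matrix(permutations)) nrow(permutations) else permutations,
    seed = seed
  )
}

#' Homogeneity of multivariate dispersions
#'
#' Distance of each sample to its group centroid in the PCoA embedding
#' (imaginary-axis contributions subtracted, the standard correction for
#' non-Euclidean dissimilarities), an F statistic over group means and a
#' permutation p on the residuals, via [vegan::betadisper()] and
#' [vegan::permutest()]. Groups of size 1 carry no dispersion information
#' and are flagged.
#'
#' @inheritParams permanova
#' @return list with `group_mean_distance`, `f_statistic`, `p_value`,
#'   `n_permutations`, `seed`, `singleton_groups`.
#' @export
beta_dispersion <- function(d, groups, permutations = 999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) stopf("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2L) stopf("dispersion test requires >= 2 groups")
  singletons <- names(which(table(groups) < 2))
  if (length(singletons)) {
    # a group of one sample carries no dispersion information: flag it and
    # test homogeneity among the remaining groups
    keep <- !groups %in% singletons
    if (nlevels(droplevels(groups[keep])) < 2L) {
      stopf("fewer than 2 groups with >= 2 samples")
    }
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  if (all(d == 0)) {
    # identical samples everywhere: dispersion is exactly zero in each group
    return(list(
      group_mean_distance = tapply(rep(0, length(groups)), groups, mean),
      f_statistic = 0, p_value = 1,
      n_permutations = if (is.matrix(permutations)) nrow(permutations) else permutations,
      seed = seed, singleton_groups = singletons
    ))
  }
  mod <- vegan::betadisper(d, groups, type = "centroid")
  # two-sample groups make the within-group distances pairwise equal, which
  # permutest flags as a near-perfect fit; the statistic itself is still valid
  pt <- with_seed(seed,
                  suppressWarnings(vegan::permutest(mod,
                                                    permutations = permutations)))
  list(
    group_mean_distance = tapply(mod$distances, groups, mean),
    f_statistic = pt$tab$F[1],
    p_value = pt$tab$`Pr(>F)`[1],
    n_permutations = if (is.matrix(permutations)) nrow(permutations) else permutations,
    seed = seed,
    singleton_groups = singletons
  )
}
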