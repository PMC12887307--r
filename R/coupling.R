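#' Mantel test between two distance matrices
#'
#' Rank (or product-moment) correlation between the strictly-upper-triangle
#' entries of two distance matrices over the same samples, with a permutation
#' null built by jointly permuting the rows and columns of the second matrix.
#' The default p-value is two-sided on |rho| with the
#' \eqn{(\mathrm{count} + 1)/(n_{perm} + 1)} convention; a one-sided
#' (positive association) p is available. With `exact = TRUE` and up to 7
#' samples, all \eqn{n!} label permutations are enumerated instead of
#' sampled.
#'
#' @param dm_a,dm_b `dist` objects or symmetric matrices with identical
#'   sample labels in identical order; at least 4 samples.
#' @param method correlation flavour passed to [stats::cor()]
#'   (default `"spearman"`).
#' @param permutations number of random permutations.
#' @param seed RNG seed (NULL = current stream).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param exact enumerate all permutations (n <= 7 only).
#' @return list with `rho`, `p_value`, `n_permutations`, `seed`,
#'   `alternative`.
#' @export
mantel_test <- function(dm_a, dm_b, method = "spearman", permutations = 999,
                        seed = NULL, alternative = c("two.sided", "greater"),
                        exact = FALSE) {
  alternative <- match.arg(alternative)
  ma <- as.matrix(stats::as.dist(dm_a))
  mb <- as.matrix(stats::as.dist(dm_b))
  if (!identical(dim(ma), dim(mb))) stopf("distance matrices differ in size")
  la <- rownames(ma)
  lb <- rownames(mb)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stopf("distance-matrix labels disagree: %s vs %s", la[1], lb[1])
  }
  n <- nrow(ma)
  if (n < 4L) stopf("Mantel test requires at least 4 samples")

  ut <- upper.tri(ma)
  rho_obs <- stats::cor(ma[ut], mb[ut], method = method)

  perms <- if (exact) {
    if (n > 7L) stopf("exact enumeration limited to n <= 7")
    all_permutations(n)[-1L, , drop = FALSE]    # drop the identity
  } else {
    with_seed(seed, t(replicate(permutations, sample.int(n))))
  }
  rho_null <- apply(perms, 1, function(p) {
    stats::cor(ma[ut], mb[p, p][ut], method = method)
  })
  count <- if (alternative == "two.sided") {
    sum(abs(rho_null) >= abs(rho_obs) - 1e-12)
  } else {
    sum(rho_null >= rho_obs - 1e-12)
  }
  list(
    rho = rho_obs,
    p_value = (count + 1) / (nrow(perms) + 1),
    n_permutations = nrow(perms),
    seed = seed,
    alternative = alternative
  )
}

# All n! permutations of 1:n as rows, identity first.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  blocks <- lapply(rev(seq_len(n)), function(pos) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, setdiff(seq_len(n), pos)] <- sub
    block
  })
  do.call(rbind, blocks)
}

#' Molecular-weight-binned DOM series intensities
#'
#' Sums assigned-formula intensities into half-open molecular-weight bins
#' `[lo, lo + width)` of the neutral monoisotopic mass, separately per
#' heteroatom series (CHO, CHNO, CHOS, ...), over a configurable mass range.
#' Masses outside the range are excluded; empty bins are reported as zero.
#'
#' @param assigned_samples named list of assigned samples
#'   (see [assign_peaklist()]).
#' @param bin_width bin width in Da (default 50).
#' @param mass_range `c(lo, hi)` neutral-mass range (default 200-600 Da).
#' @return numeric matrix, rows = `series_binlo` (e.g. `"CHO_250"`),
#'   columns = samples.
#' @export
dom_series_bins <- function(assigned_samples, bin_width = 50,
                            mass_range = c(200, 600)) {
  stopifnot(bin_width > 0, length(mass_range) == 2L)
  breaks <- seq(mass_range[1], mass_range[2], by = bin_width)
  lows <- breaks[-length(breaks)]
  per_sample <- lapply(assigned_samples, function(s) {
    a <- as_assigned_frame(s)
    inside <- a$neutral_mass >= mass_range[1] & a$neutral_mass < mass_range[2]
    a <- a[inside, , drop = FALSE]
    bin <- lows[findInterval(a$neutral_mass, breaks)]
    key <- paste0(a$series, "_", bin)
    tapply(a$intensity, key, sum)
  })
  series <- sort(unique(unlist(lapply(per_sample, names))))
  out <- sapply(per_sample, function(v) {
    x <- stats::setNames(rep(0, length(series)), series)
    x[names(v)] <- v
    x
  })
  out <- matrix(out, nrow = length(series),
                dimnames = list(series, names(assigned_samples)))
  out
}

#' Genus x DOM-series Spearman correlation grid
#'
#' Spearman rank correlation (average ranks for ties) between each genus's
#' relative abundance and each (series, mass-bin) summed intensity across the
#' shared samples. Cells with |rho| below the display threshold are masked,
#' as are cells undefined because one vector is constant.
#'
#' @param genus_abundance genus x sample matrix
#'   (see [genus_top_abundance()]).
#' @param dom_bins (series, bin) x sample matrix
#'   (see [dom_series_bins()]).
#' @param threshold minimum |rho| to display (default 0.3).
#' @return list of class `ces_correlation_grid`: `rho` (full matrix),
#'   `display` (masked copy, NA where hidden), `masked_reason`, `threshold`,
#'   `samples`.
#' @export
genus_dom_correlation_grid <- function(genus_abundance, dom_bins,
                                       threshold = 0.3) {
  shared <- intersect(colnames(genus_abundance), colnames(dom_bins))
  if (length(shared) < 4L) stopf("need at least 4 shared samples")
  g <- genus_abundance[, shared, drop = FALSE]
  d <- dom_bins[, shared, drop = FALSE]
  rho <- suppressWarnings(stats::cor(t(g), t(d), method = "spearman"))
  reason <- matrix("", nrow(rho), ncol(rho), dimnames = dimnames(rho))
  reason[is.na(rho)] <- "undefined (constant vector)"
  reason[!is.na(rho) & abs(rho) < threshold] <- "below threshold"
  display <- rho
  display[reason != ""] <- NA
  structure(
    list(rho = rho, display = display, masked_reason = reason,
         threshold = threshold, samples = shared),
    class = "ces_correlation_grid"
  )
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Sup-norm distance between the empirical CDFs of two samples (used here to
#' compare NOSC distributions between time points), with the asymptotic
#' two-sample p-value by default or the exact small-sample p via
#' `exact = TRUE`.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @param exact passed to [stats::ks.test()].
#' @return list with `d_statistic`, `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stopf("both samples need at least 2 values")
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(d_statistic = unname(kt$statistic), p_value = kt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Linear versus logarithmic diversity-coupling fit
#'
#' Fits both `y = a + b x` and `y = a + b ln(x)` by ordinary least squares to
#' paired (microbial Shannon, DOM chemodiversity) points and reports each
#' fit's R-squared and slope p-value, preferring the form with higher
#' R-squared. A better logarithmic fit means chemodiversity falls ever more
#' steeply per unit of microbial-diversity loss at the low-diversity end.
#'
#' @param microbial_h predictor (microbial Shannon index); must be positive
#'   for the logarithmic form.
#' @param chem_h response (DOM chemodiversity).
#' @return list of class `ces_fit_comparison`: `linear` and `log` (each
#'   `slope`, `intercept`, `r_squared`, `p_slope`), and `preferred`.
#' @export
diversity_fit <- function(microbial_h, chem_h) {
  stopifnot(length(microbial_h) == length(chem_h))
  if (length(microbial_h) < 3L) stopf("need at least 3 points")
  if (any(microbial_h <= 0)) {
    stopf("logarithmic fit undefined: non-positive microbial H at point(s) %s",
          paste(which(microbial_h <= 0), collapse = ", "))
  }
  describe <- function(fit) {
    sm <- suppressWarnings(summary(fit))  # degenerate fits handled below
    co <- sm$coefficients
    tss <- sum((chem_h - mean(chem_h))^2)
    list(
      intercept = unname(co[1, 1]),
      slope = if (nrow(co) > 1) unname(co[2, 1]) else 0,
      # a constant response explains nothing: report 0, not NaN
      r_squared = if (tss == 0) 0 else sm$r.squared,
      p_slope = if (nrow(co) > 1 && ncol(co) >= 4) unname(co[2, 4]) else NA_real_
    )
  }
  lin <- describe(stats::lm(chem_h ~ microbial_h))
  lg <- describe(stats::lm(chem_h ~ log(microbial_h)))
  structure(
    list(linear = lin, log = lg,
         preferred = if (lg$r_squared > lin$r_squared) "log" else "linear"),
    class = "ces_fit_comparison"
  )
}
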