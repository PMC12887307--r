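#' DOM peak-list scenario
#'
#' Parameters of the synthetic FT-ICR-MS survey: per-time-point counts of
#' CHO, CHNO and CHOS formulas, per-time-point compound-class mixtures over
#' the seven van Krevelen classes, the instrument mass window, the ppm-scale
#' mass noise and the lognormal intensity model. Defaults emulate the study
#' trajectory: CHOS formulas declining 682 -> 518 -> 452 and CHNO rising
#' 3046 -> 3182 -> 3448 across the three sampling days, class mixtures
#' drifting toward lignin/CRAM-like and aliphatic/peptide material, and
#' intensity dispersion (lognormal sdlog 1.0 -> 1.10 -> 1.45) growing as a
#' few recalcitrant compounds come to dominate the pool, so richness and
#' evenness losses jointly drive the chemodiversity decline. The CHO counts
#' (4375 -> 3000 -> 2200) are free parameters of the emulation.
#'
#' @param time_points labels of the sampling time points.
#' @param n_replicates samples per time point (replicates share the time
#'   point's formula set; masses and intensities are re-drawn per sample).
#' @param n_cho,n_chno,n_chos formula counts per time point.
#' @param class_mixture 7 x n_timepoints column-stochastic matrix of class
#'   probabilities (rows ordered as [default_class_scheme()]), or a single
#'   probability vector recycled across time points.
#' @param mass_range instrument window in Da.
#' @param ppm_noise_sd Gaussian mass-error SD in ppm.
#' @param intensity_meanlog,intensity_sdlog lognormal intensity parameters;
#'   `intensity_sdlog` may be per-time-point.
#' @param seed RNG seed.
#' @return object of class `ces_dom_scenario`.
#' @export
dom_scenario <- function(time_points = c("day8", "day33", "day54"),
                         n_replicates = 2,
                         n_cho = c(4375, 3000, 2200),
                         n_chno = c(3046, 3182, 3448),
                         n_chos = c(682, 518, 452),
                         class_mixture = NULL,
                         mass_range = c(100, 800),
                         ppm_noise_sd = 0.2,
                         intensity_meanlog = 10,
                         intensity_sdlog = c(1.0, 1.10, 1.45),
                         seed = 1) {
  k <- length(time_points)
  stopifnot(length(n_cho) == k, length(n_chno) == k, length(n_chos) == k)
  if (is.null(class_mixture)) {
    class_mixture <- default_class_mixture()[, seq_len(min(k, 3)), drop = FALSE]
    if (k > 3) stopf("supply class_mixture explicitly for > 3 time points")
  }
  if (is.vector(class_mixture)) {
    class_mixture <- matrix(class_mixture, nrow = length(class_mixture), ncol = k)
  }
  if (nrow(class_mixture) != 7L || ncol(class_mixture) != k) {
    stopf("class_mixture must be 7 classes x %d time points", k)
  }
  if (any(abs(colSums(class_mixture) - 1) > 1e-8)) {
    stopf("class mixtures must each sum to 1")
  }
  rownames(class_mixture) <- default_class_scheme()$label
  if (mass_range[1] < 0 || mass_range[1] >= mass_range[2]) {
    stopf("malformed mass_range")
  }
  intensity_sdlog <- rep_len(intensity_sdlog, k)
  structure(
    list(time_points = time_points, n_replicates = n_replicates,
         n_cho = n_cho, n_chno = n_chno, n_chos = n_chos,
         class_mixture = class_mixture, mass_range = mass_range,
         ppm_noise_sd = ppm_noise_sd,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog, seed = seed),
    class = "ces_dom_scenario"
  )
}

# Class-mixture defaults: lignin/CRAM-like and aliphatic/peptide fractions
# follow the study's reported trajectory; the minor classes share the
# remainder and decline.
default_class_mixture <- function() {
  m <- cbind(
    day8  = c(0.080, 0.1371, 0.050, 0.040, 0.5850, 0.060, 0.0479),
    day33 = c(0.030, 0.2559, 0.020, 0.015, 0.6336, 0.025, 0.0205),
    day54 = c(0.020, 0.3027, 0.015, 0.010, 0.6149, 0.020, 0.0174)
  )
  rownames(m) <- default_class_scheme()$label
  sweep(m, 2, colSums(m), "/")
}

# Rejection-sample `n` distinct valid formulas of one heteroatom series from
# one compound-class H/C-O/C box. RNG state is the caller's.
sample_class_formulas <- function(n, class_label, series,
                                  scheme, config, mass_range) {
  if (n == 0) return(NULL)
  r <- scheme[scheme$label == class_label, ]
  if (nrow(r) != 1L) stopf("unknown compound class '%s'", class_label)
  hc_lo <- max(r$hc_lo, config$hc_range[1])
  hc_hi <- min(r$hc_hi, config$hc_range[2])
  oc_lo <- max(r$oc_lo, 1e-9)
  oc_hi <- min(r$oc_hi, config$oc_range[2])
  if (hc_lo >= hc_hi || oc_lo >= oc_hi) {
    stopf("class '%s' box is empty within the configured H/C-O/C bounds",
          class_label)
  }

  seen <- character(0)
  kept <- vector("list", 0)
  for (round in seq_len(60)) {
    m <- max(500L, 3L * n)
    cand <- data.frame(
      c = sample(seq.int(config$c_range[1], config$c_range[2]), m, replace = TRUE)
    )
    cand$h <- as.integer(round(cand$c * stats::runif(m, hc_lo, hc_hi)))
    cand$o <- pmax(config$o_range[1],
                   as.integer(round(cand$c * stats::runif(m, oc_lo, oc_hi))))
    cand$n <- switch(series,
      CHO = 0L, CHOS = 0L,
      CHNO = sample(1:4, m, replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
    )
    cand$s <- switch(series,
      CHO = 0L, CHNO = 0L,
      CHOS = sample(1:2, m, replace = TRUE, prob = c(0.85, 0.15))
    )
    odd <- (cand$h + cand$n) %% 2 == 1       # force integer DBE
    cand$h[odd] <- cand$h[odd] + 1L
    desc <- formula_descriptors(cand)
    in_box <- desc$hc >= r$hc_lo & desc$oc >= r$oc_lo &
      (if (r$hc_hi_closed) desc$hc <= r$hc_hi else desc$hc < r$hc_hi) &
      (if (r$oc_hi_closed) desc$oc <= r$oc_hi else desc$oc < r$oc_hi)
    ok <- in_box & formula_valid(desc, config) &
      desc$neutral_mass >= mass_range[1] & desc$neutral_mass <= mass_range[2] &
      # the deprotonated ion must also sit inside the acquisition window
      desc$theoretical_mz >= config$mz_range[1] &
      desc$theoretical_mz <= config$mz_range[2]
    desc <- desc[ok, , drop = FALSE]
    if (round == 1L && nrow(desc) == 0L) {
      stopf("class '%s' (%s series) is unsatisfiable within the element bounds",
            class_label, series)
    }
    fresh <- !desc$formula %in% seen & !duplicated(desc$formula)
    desc <- desc[fresh, , drop = FALSE]
    seen <- c(seen, desc$formula)
    kept[[length(kept) + 1L]] <- desc
    if (length(seen) >= n) break
  }
  out <- do.call(rbind, kept)
  if (nrow(out) < n) {
    stopf("could not draw %d distinct '%s' %s formulas (box too small)",
          n, class_label, series)
  }
  out <- out[seq_len(n), , drop = FALSE]
  out$compound_class <- class_label
  out
}

#' Generate synthetic DOM peak lists with ground-truth formulas
#'
#' For each time point, draws the configured numbers of CHO, CHNO and CHOS
#' formulas by rejection sampling from the compound-class H/C-O/C boxes
#' (classes multinomially allocated per the time point's mixture); every
#' truth formula passes the assignment module's validity rules. Each
#' replicate sample then observes the time point's formula set as a peak
#' list: m/z is the theoretical \eqn{[M-H]^-} value perturbed by Gaussian ppm
#' noise, intensity is lognormal.
#'
#' @param scenario a [dom_scenario()].
#' @param config assignment validity rules the truth must satisfy.
#' @param scheme compound-class scheme.
#' @return list with `peaklists` (named list of `mz`/`intensity` data
#'   frames, sorted by m/z), `truth` (per-sample frames mapping each peak to
#'   its source formula, plus per-time-point formula tables), `samples`
#'   (sample / time-point manifest) and the scenario.
#' @export
gen_dom_peaklists <- function(scenario = dom_scenario(),
                              config = assignment_config(),
                              scheme = default_class_scheme()) {
  stopifnot(inherits(scenario, "ces_dom_scenario"))
  with_seed(scenario$seed, {
    peaklists <- list()
    truth_samples <- list()
    truth_formulas <- list()
    manifest <- NULL
    for (i in seq_along(scenario$time_points)) {
      tp <- scenario$time_points[i]
      counts <- c(CHO = scenario$n_cho[i], CHNO = scenario$n_chno[i],
                  CHOS = scenario$n_chos[i])
      parts <- list()
      for (series in names(counts)) {
        if (counts[[series]] == 0) next
        classes <- sample(rownames(scenario$class_mixture), counts[[series]],
                          replace = TRUE, prob = scenario$class_mixture[, i])
        tab <- table(classes)
        for (cl in names(tab)) {
          parts[[paste(series, cl)]] <- sample_class_formulas(
            as.integer(tab[[cl]]), cl, series, scheme, config,
            scenario$mass_range
          )
        }
      }
      formulas <- do.call(rbind, parts)
      rownames(formulas) <- NULL
      truth_formulas[[tp]] <- formulas

      for (r in seq_len(scenario$n_replicates)) {
        sample_id <- sprintf("%s_r%d", tp, r)
        nf <- nrow(formulas)
        mz <- formulas$theoretical_mz *
          (1 + stats::rnorm(nf, 0, scenario$ppm_noise_sd) * 1e-6)
        intensity <- stats::rlnorm(nf, scenario$intensity_meanlog,
                                   scenario$intensity_sdlog[i])
        ord <- order(mz)
        peaklists[[sample_id]] <- data.frame(mz = mz[ord],
                                             intensity = intensity[ord])
        tr <- formulas[ord, c("formula", "c", "h", "n", "o", "s",
                              "theoretical_mz", "series", "compound_class")]
        tr <- cbind(data.frame(sample = sample_id, mz = mz[ord],
                               intensity = intensity[ord]), tr)
        rownames(tr) <- NULL
        truth_samples[[sample_id]] <- tr
        manifest <- rbind(manifest,
                          data.frame(sample = sample_id, time_point = tp,
                                     replicate = r))
      }
    }
    list(peaklists = peaklists,
         truth = list(samples = truth_samples, formulas = truth_formulas,
                      scenario = scenario),
         samples = manifest)
  })
}
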