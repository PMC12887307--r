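#' Van Krevelen compound-class scheme
#'
#' The seven-class stoichiometric classification of DOM formulas by position
#' in H/C versus O/C space. Rules are evaluated in order and the first match
#' wins; a formula matching no box is labelled `"unclassified"`. All lower
#' interval bounds are inclusive; upper bounds are inclusive or exclusive per
#' the `hc_hi_closed` / `oc_hi_closed` flags. The default boxes are the
#' conventional ones used for PPL-extracted DOM and are fully replaceable via
#' `class_scheme()` should a study define its own supplementary boundaries.
#'
#' @param label class labels, `hc_lo` etc. interval bounds, `*_closed`
#'   logical upper-bound closure flags.
#' @return data frame of class `ces_class_scheme`.
#' @export
class_scheme <- function(label, hc_lo, hc_hi, oc_lo, oc_hi,
                         hc_hi_closed = TRUE, oc_hi_closed = TRUE) {
  s <- data.frame(
    label = label, hc_lo = hc_lo, hc_hi = hc_hi, oc_lo = oc_lo, oc_hi = oc_hi,
    hc_hi_closed = hc_hi_closed, oc_hi_closed = oc_hi_closed,
    stringsAsFactors = FALSE
  )
  if (any(s$hc_lo > s$hc_hi) || any(s$oc_lo > s$oc_hi)) {
    stopf("malformed class boxes: lower bound exceeds upper bound")
  }
  class(s) <- c("ces_class_scheme", "data.frame")
  s
}

#' @rdname class_scheme
#' @export
default_class_scheme <- function() {
  class_scheme(
    label = c("lipids", "aliphatic/peptides", "carbohydrates",
              "unsaturated hydrocarbons", "lignin/CRAM-like", "tannins",
              "aromatic structures"),
    hc_lo = c(1.5, 1.5, 1.5, 0.7, 0.7, 0.5, 0.2),
    hc_hi = c(2.0, 2.2, 2.4, 1.5, 1.5, 1.5, 0.7),
    hc_hi_closed = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    oc_lo = c(0.0, 0.3, 0.67, 0.0, 0.1, 0.67, 0.0),
    oc_hi = c(0.3, 0.67, 1.2, 0.1, 0.67, 1.2, 0.67),
    oc_hi_closed = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Classify formulas by H/C and O/C position
#'
#' @param hc,oc numeric vectors of elemental ratios (equal length).
#' @param scheme a [class_scheme()]; first matching rule wins.
#' @return character vector of class labels, `"unclassified"` when no box
#'   matches.
#' @examples
#' classify_formula(c(1.2, 1.8, 2.6), c(0.4, 0.1, 0.5))
#' @export
classify_formula <- function(hc, oc, scheme = default_class_scheme()) {
  stopifnot(length(hc) == length(oc))
  out <- rep("unclassified", length(hc))
  # iterate rules last-to-first so that earlier rules overwrite: first match wins
  for (i in rev(seq_len(nrow(scheme)))) {
    r <- scheme[i, ]
    hit <- hc >= r$hc_lo & oc >= r$oc_lo &
      (if (r$hc_hi_closed) hc <= r$hc_hi else hc < r$hc_hi) &
      (if (r$oc_hi_closed) oc <= r$oc_hi else oc < r$oc_hi)
    out[hit] <- r$label
  }
  out
}

#' Assign molecular formulas to a peak list
#'
#' For each peak the candidates from [candidate_formulas()] are ranked by
#' |ppm error|, then fewest N+S atoms, then lowest DBE, then lexicographic
#' element counts — a deterministic tie-break. Peaks with no candidate are
#' returned unassigned. When two peaks in one sample resolve to the same
#' formula their intensities are summed into a single record (the retained
#' m/z and ppm error are those of the closest peak).
#'
#' @param peaks data frame with columns `mz` and `intensity`.
#' @param config an [assignment_config()].
#' @param scheme a [class_scheme()] for compound classification.
#' @return list of class `ces_assigned_sample` with elements `assigned`
#'   (descriptor rows plus `mz`, `intensity`, `ppm_error`, `n_candidates`,
#'   `compound_class`, `n_peaks`), `unassigned`, `config`, `scheme`.
#' @export
assign_peaklist <- function(peaks, config = assignment_config(),
                            scheme = default_class_scheme()) {
  stopifnot(is.data.frame(peaks))
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    stopf("peaks must have `mz` and `intensity` columns")
  }
  if (nrow(peaks) == 0L) stopf("assign_peaklist() requires at least one peak")
  if (any(peaks$intensity <= 0)) stopf("peak intensities must be positive")

  grid <- candidate_base_grid(config)
  rows <- vector("list", nrow(peaks))
  unassigned <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    cand <- candidate_formulas(peaks$mz[i], config, grid = grid)
    if (nrow(cand) == 0L) {
      unassigned[i] <- TRUE
      next
    }
    best <- cand[order(abs(cand$ppm_error), cand$n + cand$s, cand$dbe,
                       cand$c, cand$h, cand$n, cand$o, cand$s), , drop = FALSE][1, ]
    best$n_candidates <- nrow(cand)
    best$mz <- peaks$mz[i]
    best$intensity <- peaks$intensity[i]
    rows[[i]] <- best
  }
  assigned <- do.call(rbind, rows[!unassigned])

  if (!is.null(assigned) && nrow(assigned)) {
    # merge duplicate formulas within the sample by summing intensity
    assigned <- assigned[order(assigned$formula, abs(assigned$ppm_error)), ]
    total <- tapply(assigned$intensity, assigned$formula, sum)
    npk <- tapply(assigned$intensity, assigned$formula, length)
    first <- !duplicated(assigned$formula)
    assigned <- assigned[first, , drop = FALSE]
    assigned$intensity <- as.numeric(total[assigned$formula])
    assigned$n_peaks <- as.integer(npk[assigned$formula])
    assigned$compound_class <- classify_formula(assigned$hc, assigned$oc, scheme)
    assigned <- assigned[order(assigned$mz), , drop = FALSE]
    rownames(assigned) <- NULL
  } else {
    assigned <- NULL
  }

  structure(
    list(
      assigned = assigned,
      unassigned = peaks[unassigned, , drop = FALSE],
      config = config,
      scheme = scheme,
      n_input = nrow(peaks)
    ),
    class = "ces_assigned_sample"
  )
}

as_assigned_frame <- function(x) {
  if (inherits(x, "ces_assigned_sample")) x <- x$assigned
  if (is.null(x) || nrow(x) == 0L) stopf("no assigned formulas in sample")
  x
}

#' Compound-class relative abundance
#'
#' Fraction of the DOM pool in each of the seven compound classes (plus
#' `"unclassified"`), weighted by spectral intensity (default, matching the
#' intensity-scaled van Krevelen representation) or by formula count.
#'
#' @param assigned a `ces_assigned_sample` or its `assigned` data frame.
#' @param weighting `"intensity"` or `"count"`.
#' @param scheme scheme whose labels order the output.
#' @return named numeric vector over class labels, summing to 1.
#' @export
class_abundance <- function(assigned, weighting = c("intensity", "count"),
                            scheme = default_class_scheme()) {
  weighting <- match.arg(weighting)
  a <- as_assigned_frame(assigned)
  w <- if (weighting == "intensity") a$intensity else rep(1, nrow(a))
  labels <- c(scheme$label, "unclassified")
  tot <- vapply(labels, function(l) sum(w[a$compound_class == l]), 0)
  tot / sum(tot)
}

#' DOM chemodiversity (Shannon index on peak intensities)
#'
#' \eqn{H = -\sum p_i \ln p_i} over the intensity shares of the assigned
#' formulas, in nats.
#'
#' @param assigned a `ces_assigned_sample`, its `assigned` frame, or a bare
#'   numeric vector of positive intensities.
#' @return Shannon index in nats.
#' @export
chemodiversity <- function(assigned) {
  x <- if (is.numeric(assigned)) assigned else as_assigned_frame(assigned)$intensity
  if (any(x <= 0)) stopf("chemodiversity() requires positive intensities")
  shannon_entropy(x)
}

#' Shared and unique formula sets between two samples
#'
#' Partitions the assigned formulas of two samples (keyed on exact element
#' counts) into shared, unique-to-a and unique-to-b sets, with per-class
#' tallies of each partition.
#'
#' @param a,b assigned samples (see [assign_peaklist()]).
#' @return list with data frames `shared`, `unique_a`, `unique_b` and a
#'   `class_tally` data frame (class x partition counts).
#' @export
compare_formula_sets <- function(a, b) {
  fa <- as_assigned_frame(a)
  fb <- as_assigned_frame(b)
  shared_keys <- intersect(fa$formula, fb$formula)
  out <- list(
    shared = fa[fa$formula %in% shared_keys, , drop = FALSE],
    unique_a = fa[!fa$formula %in% shared_keys, , drop = FALSE],
    unique_b = fb[!fb$formula %in% shared_keys, , drop = FALSE]
  )
  labels <- sort(unique(c(fa$compound_class, fb$compound_class)))
  tally <- sapply(out, function(d) {
    vapply(labels, function(l) sum(d$compound_class == l), 0L)
  })
  out$class_tally <- data.frame(compound_class = labels, tally,
                                row.names = NULL, check.names = FALSE)
  out
}
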