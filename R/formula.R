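#' @name cesdyn-masses
#' @title Monoisotopic mass constants
#' @description Monoisotopic atomic masses (Da) used for all exact-mass
#'   arithmetic, stored to at least ten significant digits, and the proton
#'   mass used for the deprotonated \eqn{[M-H]^-} ion.
#' @keywords internal
NULL

MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Proton mass (Da): mass of H minus the electron mass.
PROTON_MASS <- 1.00727646688

#' Exact neutral monoisotopic mass of CHNOS formulas
#'
#' @param formulas data frame with integer columns `c`, `h`, `n`, `o`, `s`
#'   (element counts; `n`, `o`, `s` may be absent and default to zero).
#' @return numeric vector of neutral monoisotopic masses in Da.
#' @export
neutral_mass <- function(formulas) {
  f <- normalize_formulas(formulas)
  MONOISOTOPIC_MASS[["C"]] * f$c + MONOISOTOPIC_MASS[["H"]] * f$h +
    MONOISOTOPIC_MASS[["N"]] * f$n + MONOISOTOPIC_MASS[["O"]] * f$o +
    MONOISOTOPIC_MASS[["S"]] * f$s
}

normalize_formulas <- function(formulas) {
  if (is.numeric(formulas) && !is.null(names(formulas))) {
    formulas <- as.data.frame(as.list(formulas))
  }
  stopifnot(is.data.frame(formulas))
  for (el in c("n", "o", "s")) if (is.null(formulas[[el]])) formulas[[el]] <- 0L
  if (is.null(formulas$c) || is.null(formulas$h)) {
    stopf("formulas need at least `c` and `h` columns")
  }
  formulas[c("c", "h", "n", "o", "s")]
}

#' Compact Hill-style formula labels (e.g. "C6H12O6")
#' @param formulas data frame of element counts (see [neutral_mass()]).
#' @return character vector of formula labels, usable as set keys.
#' @export
formula_string <- function(formulas) {
  f <- normalize_formulas(formulas)
  paste0(
    "C", f$c, "H", f$h,
    ifelse(f$n > 0, paste0("N", f$n), ""),
    ifelse(f$o > 0, paste0("O", f$o), ""),
    ifelse(f$s > 0, paste0("S", f$s), "")
  )
}

#' Molecular descriptors for CHNOS formulas
#'
#' Computes, for each formula, the neutral monoisotopic mass, the theoretical
#' deprotonated ion m/z, the H/C and O/C elemental ratios, double-bond
#' equivalents \eqn{DBE = C - H/2 + N/2 + 1}, the nominal oxidation state of
#' carbon \eqn{NOSC = 4 - (4C + H - 3N - 2O - 2S)/C}, and the heteroatom
#' series (CHO, CHNO, CHOS or CHNOS).
#'
#' NOSC summarizes how oxidized the average carbon is: -4 for fully reduced
#' carbon (CH4) up to +4 for fully oxidized carbon (CO2). More negative values
#' indicate more reduced, typically less bioavailable material under oxygen
#' limitation.
#'
#' @param formulas data frame with element-count columns `c`, `h` and
#'   optionally `n`, `o`, `s`. `c >= 1` is required.
#' @return the input counts with descriptor columns appended:
#'   `formula`, `neutral_mass`, `theoretical_mz`, `hc`, `oc`, `dbe`, `nosc`,
#'   `series`.
#' @examples
#' formula_descriptors(data.frame(c = 6, h = 12, o = 6))
#' @export
formula_descriptors <- function(formulas) {
  f <- normalize_formulas(formulas)
  if (any(f$c < 1)) stopf("formula_descriptors() requires c >= 1")
  f$formula <- formula_string(f)
  f$neutral_mass <- neutral_mass(f)
  f$theoretical_mz <- f$neutral_mass - PROTON_MASS
  f$hc <- f$h / f$c
  f$oc <- f$o / f$c
  f$dbe <- f$c - f$h / 2 + f$n / 2 + 1
  f$nosc <- 4 - (4 * f$c + f$h - 3 * f$n - 2 * f$o - 2 * f$s) / f$c
  f$series <- ifelse(
    f$n > 0 & f$s > 0, "CHNOS",
    ifelse(f$n > 0, "CHNO", ifelse(f$s > 0, "CHOS", "CHO"))
  )
  f
}

#' Formula-assignment configuration
#'
#' Validity rules for molecular-formula assignment of negative-mode
#' (\eqn{[M-H]^-}) FT-ICR-MS peaks: mass tolerance, element-count bounds,
#' elemental-ratio windows and the DBE and NOSC plausibility ranges.
#' These are the standard conservative rules for solid-phase-extracted DOM;
#' every bound is configurable.
#'
#' @param tolerance_ppm maximum |mass error| for a candidate, in ppm.
#' @param c_range,h_range,n_range,o_range,s_range integer element-count
#'   bounds `c(min, max)`.
#' @param hc_range H/C window (closed).
#' @param oc_range O/C window; the lower bound is exclusive (O >= 1 already
#'   forces O/C > 0), the upper inclusive.
#' @param dbe_range allowed double-bond-equivalent range; DBE must also be an
#'   integer (even-electron neutral molecule).
#' @param nosc_range allowed nominal-oxidation-state range; the chemical
#'   limits are -4 (CH4-like) and +4 (CO2-like).
#' @param mz_range instrument acquisition window in Da.
#' @return an object of class `ces_assignment_config`.
#' @export
assignment_config <- function(tolerance_ppm = 1.0,
                              c_range = c(4L, 50L),
                              h_range = c(4L, 100L),
                              n_range = c(0L, 4L),
                              o_range = c(1L, 40L),
                              s_range = c(0L, 2L),
                              hc_range = c(0.3, 2.5),
                              oc_range = c(0, 1.2),
                              dbe_range = c(0, 25),
                              nosc_range = c(-4, 4),
                              mz_range = c(100, 800)) {
  ranges <- list(
    c_range = c_range, h_range = h_range, n_range = n_range,
    o_range = o_range, s_range = s_range, hc_range = hc_range,
    oc_range = oc_range, dbe_range = dbe_range, nosc_range = nosc_range,
    mz_range = mz_range
  )
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stopf("%s must be a finite, ordered pair", nm)
    }
  }
  if (tolerance_ppm < 0) stopf("tolerance_ppm must be >= 0")
  structure(
    c(list(tolerance_ppm = tolerance_ppm), ranges),
    class = "ces_assignment_config"
  )
}

# Validity of descriptor rows under an assignment config. Returns a logical
# vector; the mass-window check is deliberately excluded (it applies to the
# observed peak, not the formula).
formula_valid <- function(desc, config) {
  in_range <- function(x, r) x >= r[1] & x <= r[2]
  near_int <- abs(desc$dbe - round(desc$dbe)) < 1e-9
  desc$c >= 1 & desc$h >= 1 &
    in_range(desc$c, config$c_range) &
    in_range(desc$h, config$h_range) &
    in_range(desc$n, config$n_range) &
    in_range(desc$o, config$o_range) &
    in_range(desc$s, config$s_range) &
    in_range(desc$hc, config$hc_range) &
    desc$oc > config$oc_range[1] & desc$oc <= config$oc_range[2] &
    near_int & in_range(desc$dbe, config$dbe_range) &
    in_range(desc$nosc, config$nosc_range)
}

# Pre-computed (C, N, O, S) grid sorted by base mass; H is solved per peak.
candidate_base_grid <- function(config) {
  g <- expand.grid(
    c = seq.int(config$c_range[1], config$c_range[2]),
    n = seq.int(config$n_range[1], config$n_range[2]),
    o = seq.int(config$o_range[1], config$o_range[2]),
    s = seq.int(config$s_range[1], config$s_range[2]),
    KEEP.OUT.ATTRS = FALSE
  )
  g$base <- MONOISOTOPIC_MASS[["C"]] * g$c + MONOISOTOPIC_MASS[["N"]] * g$n +
    MONOISOTOPIC_MASS[["O"]] * g$o + MONOISOTOPIC_MASS[["S"]] * g$s
  g[order(g$base), , drop = FALSE]
}

#' Enumerate candidate molecular formulas for one observed m/z
#'
#' Exhaustively lists every CHNOS formula whose theoretical \eqn{[M-H]^-} m/z
#' falls within `tolerance_ppm` of the observed peak and that passes all
#' validity rules of the configuration. Rather than scanning the full
#' five-element grid, the hydrogen count is solved from the residual mass over
#' a (C, N, O, S) grid, which is exact because consecutive H counts are spaced
#' ~1.008 Da apart, far wider than any ppm-scale window.
#'
#' @param mz observed m/z (Da, singly charged, negative mode).
#' @param config an [assignment_config()].
#' @param grid optional pre-computed grid from repeated calls (internal use).
#' @return data frame of candidates with descriptor columns and `ppm_error`,
#'   sorted by |ppm_error|. Zero rows is a valid result.
#' @examples
#' glucose_mz <- 180.063388 - 1.00727646688
#' candidate_formulas(glucose_mz, assignment_config())
#' @export
candidate_formulas <- function(mz, config = assignment_config(), grid = NULL) {
  stopifnot(length(mz) == 1L, is.finite(mz))
  if (mz < config$mz_range[1] || mz > config$mz_range[2]) {
    stopf("mz %.4f outside the instrument window [%g, %g]",
          mz, config$mz_range[1], config$mz_range[2])
  }
  if (is.null(grid)) grid <- candidate_base_grid(config)
  target <- mz + PROTON_MASS            # neutral mass to match
  tol_da <- config$tolerance_ppm * 1e-6 * mz
  m_h <- MONOISOTOPIC_MASS[["H"]]

  # Window of base masses that can reach the target with an allowed H count.
  lo <- target - tol_da - m_h * config$h_range[2]
  hi <- target + tol_da - m_h * config$h_range[1]
  i1 <- findInterval(lo, grid$base) + 1L
  i2 <- findInterval(hi, grid$base)
  if (i2 < i1) return(empty_candidates())
  sub <- grid[i1:i2, , drop = FALSE]

  h_lo <- ceiling((target - tol_da - sub$base) / m_h - 1e-9)
  h_hi <- floor((target + tol_da - sub$base) / m_h + 1e-9)
  span <- h_hi - h_lo
  keep <- span >= 0
  if (!any(keep)) return(empty_candidates())
  sub <- sub[keep, , drop = FALSE]
  h_lo <- h_lo[keep]
  h_hi <- h_hi[keep]

  pieces <- lapply(0:max(h_hi - h_lo), function(off) {
    ok <- h_lo + off <= h_hi
    if (!any(ok)) return(NULL)
    out <- sub[ok, c("c", "n", "o", "s"), drop = FALSE]
    out$h <- h_lo[ok] + off
    out
  })
  cand <- do.call(rbind, pieces)
  desc <- formula_descriptors(cand)
  desc$ppm_error <- (desc$theoretical_mz - mz) / mz * 1e6
  ok <- formula_valid(desc, config) &
    abs(desc$ppm_error) <= config$tolerance_ppm + 1e-9
  desc <- desc[ok, , drop = FALSE]
  desc <- desc[order(abs(desc$ppm_error)), , drop = FALSE]
  rownames(desc) <- NULL
  desc
}

empty_candidates <- function() {
  d <- formula_descriptors(data.frame(c = 1L, h = 1L, n = 0L, o = 0L, s = 0L))
  d$ppm_error <- NA_real_
  d[0, , drop = FALSE]
}
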