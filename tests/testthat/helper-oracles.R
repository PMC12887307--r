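# Independent oracles, deliberately written as naive brute force so they share
# no code path with the implementations they check.

# --- exact-mass constants, re-declared locally -------------------------------
.orc_mass <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)
.orc_proton <- 1.00727646688

# Full five-element grid (built once per test run).
.orc_grid_env <- new.env(parent = emptyenv())
oracle_full_grid <- function() {
  if (is.null(.orc_grid_env$g)) {
    g <- expand.grid(c = 4:50, h = 4:100, n = 0:4, o = 1:40, s = 0:2,
                     KEEP.OUT.ATTRS = FALSE)
    g$mass <- .orc_mass[["C"]] * g$c + .orc_mass[["H"]] * g$h +
      .orc_mass[["N"]] * g$n + .orc_mass[["O"]] * g$o + .orc_mass[["S"]] * g$s
    g$hc <- g$h / g$c
    g$oc <- g$o / g$c
    g$dbe <- g$c - g$h / 2 + g$n / 2 + 1
    g$nosc <- 4 - (4 * g$c + g$h - 3 * g$n - 2 * g$o - 2 * g$s) / g$c
    .orc_grid_env$g <- g
  }
  .orc_grid_env$g
}

# Brute-force candidate enumeration under the default validity rules.
oracle_candidates <- function(mz, tol_ppm = 1) {
  g <- oracle_full_grid()
  theo <- g$mass - .orc_proton
  ppm <- (theo - mz) / mz * 1e6
  keep <- abs(ppm) <= tol_ppm + 1e-9 &
    g$hc >= 0.3 & g$hc <= 2.5 &
    g$oc > 0 & g$oc <= 1.2 &
    g$dbe >= 0 & g$dbe <= 25 & abs(g$dbe - round(g$dbe)) < 1e-9 &
    g$nosc >= -4 & g$nosc <= 4
  out <- g[keep, c("c", "h", "n", "o", "s"), drop = FALSE]
  out$ppm_error <- ppm[keep]
  out[order(abs(out$ppm_error), out$c, out$h, out$n, out$o, out$s), ,
      drop = FALSE]
}

# Brute-force two-sample KS distance: sup over pooled points of the ECDF gap.
oracle_ks_d <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 0))
}

# Anderson pseudo-F and R^2 straight from the distance matrix.
oracle_permanova_stats <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.factor(groups)
  sst <- sum(m[upper.tri(m)]^2) / n
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- m[idx, idx, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ssa <- sst - ssw
  a <- nlevels(groups)
  list(pseudo_f = (ssa / (a - 1)) / (ssw / (n - a)), r_squared = ssa / sst)
}

# Exhaustive PERMANOVA p over all label permutations (identity included).
oracle_permanova_p <- function(d, groups) {
  n <- length(groups)
  perms <- cesdyn:::all_permutations(n)
  f_obs <- oracle_permanova_stats(d, groups)$pseudo_f
  f_all <- apply(perms, 1, function(p) {
    oracle_permanova_stats(d, groups[p])$pseudo_f
  })
  mean(f_all >= f_obs - 1e-12)
}

# Exhaustive Mantel p (two-sided on |rho|), identity included.
oracle_mantel_p <- function(ma, mb, method = "spearman") {
  n <- nrow(ma)
  ut <- upper.tri(ma)
  rho_obs <- cor(ma[ut], mb[ut], method = method)
  perms <- cesdyn:::all_permutations(n)
  rho_all <- apply(perms, 1, function(p) {
    cor(ma[ut], mb[p, p][ut], method = method)
  })
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

random_dist <- function(n, seed, dim = 3) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), ncol = dim)
  rownames(pts) <- paste0("s", seq_len(n))
  dist(pts)
}

# Small scenarios shared across tests (kept tiny for speed).
tiny_pressure_scenario <- function(...) {
  pressure_scenario(
    n_units = 2, duration_days = 5, dt = 300,
    phase_windows = list(c(1, 5, 15)), collapse_window = NULL,
    noise_sd = 0, temp_coupling = 0, temp_diel_amplitude = 0,
    drift_per_day = 0, seed = 42, ...
  )
}

tiny_dom_scenario <- function(...) {
  dom_scenario(
    n_cho = c(40, 30, 20), n_chno = c(25, 25, 25), n_chos = c(15, 12, 10),
    ppm_noise_sd = 0, seed = 42, ...
  )
}
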