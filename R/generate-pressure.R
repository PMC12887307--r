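#' Pressure-experiment scenario
#'
#' Parameters of the synthetic sealed-vial experiment: a set of biotic vials
#' plus one sterile control sharing a water bath, sampled on a common clock,
#' with a piecewise diel sawtooth whose target amplitude follows a
#' three-phase trajectory (high activity, collapse/recovery, late decline).
#' Defaults emulate the 54-day, 12-vial study design with a 12 h / 12 h
#' photoperiod: amplitudes 18.7 hPa (days 1-8), 7.2 hPa (days 31-45) and
#' 5.0 hPa (days 46-54), oscillation suppressed over the day 9-25 collapse
#' window with a monotone baseline decline, and linear amplitude recovery
#' between defined windows.
#'
#' @param n_units number of biotic vials.
#' @param duration_days experiment length in days.
#' @param dt sampling interval in seconds (native hardware rate 10 s; the
#'   default 60 s keeps full-study objects small and is analytically
#'   equivalent for diel-scale metrics).
#' @param photoperiod hours of light per 24 h.
#' @param phase_windows list of `c(start_day, end_day, amplitude_hPa)` or
#'   `c(start_day, end_day, amplitude_hPa, relative_sd)` target windows
#'   (inclusive days, non-overlapping). The optional fourth element scatters
#'   each vial-day's realized amplitude around the target
#'   (`amplitude * max(0, 1 + N(0, relative_sd))`), emulating the
#'   high-variability early phase versus the tightly regulated
#'   re-stabilized phase; it defaults to 0 (deterministic amplitude).
#' @param collapse_window `c(start_day, end_day)` with oscillation
#'   suppressed, or NULL.
#' @param collapse_decline baseline pressure loss per day (hPa/day) inside
#'   the collapse window.
#' @param base_pressure starting headspace pressure (hPa).
#' @param temp_mean,temp_diel_amplitude bath temperature mean and
#'   peak-to-peak diel swing (deg C).
#' @param temp_coupling abiotic pressure response (hPa per deg C).
#' @param noise_sd sensor noise SD (hPa).
#' @param drift_per_day linear sensor drift (hPa/day).
#' @param seed RNG seed; identical scenarios with identical seeds generate
#'   byte-identical data.
#' @return object of class `ces_pressure_scenario`.
#' @export
pressure_scenario <- function(n_units = 12,
                              duration_days = 54,
                              dt = 60,
                              photoperiod = 12,
                              phase_windows = list(c(1, 8, 18.7, 0.15),
                                                   c(31, 45, 7.2, 0.05),
                                                   c(46, 54, 5.0, 0.08)),
                              collapse_window = c(9, 25),
                              collapse_decline = 1.0,
                              base_pressure = 1013.25,
                              temp_mean = 30,
                              temp_diel_amplitude = 0.5,
                              temp_coupling = 0.5,
                              noise_sd = 0.5,
                              drift_per_day = 0,
                              seed = 1) {
  if (dt <= 0) stopf("dt must be positive")
  if (dt > photoperiod * 3600 / 2) {
    stopf("dt = %g s cannot resolve a %g h light phase", dt, photoperiod)
  }
  windows <- do.call(rbind, lapply(phase_windows, function(w) {
    stopifnot(length(w) %in% c(3L, 4L), w[1] <= w[2], w[3] >= 0)
    data.frame(start = w[1], end = w[2], amplitude = w[3],
               rel_sd = if (length(w) == 4L) w[4] else 0)
  }))
  if (any(windows$rel_sd < 0)) stopf("amplitude relative SD must be >= 0")
  windows <- windows[order(windows$start), ]
  if (!is.null(collapse_window)) {
    stopifnot(length(collapse_window) == 2L,
              collapse_window[1] <= collapse_window[2])
  }
  spans <- rbind(windows[c("start", "end")],
                 if (!is.null(collapse_window)) {
                   data.frame(start = collapse_window[1], end = collapse_window[2])
                 })
  spans <- spans[order(spans$start), ]
  if (any(spans$start[-1] <= spans$end[-nrow(spans)])) {
    stopf("phase/collapse windows overlap")
  }
  if (max(spans$end) > duration_days) stopf("windows extend past duration_days")
  structure(
    list(
      n_units = n_units, duration_days = duration_days, dt = dt,
      photoperiod = photoperiod, phase_windows = windows,
      collapse_window = collapse_window, collapse_decline = collapse_decline,
      base_pressure = base_pressure, temp_mean = temp_mean,
      temp_diel_amplitude = temp_diel_amplitude,
      temp_coupling = temp_coupling, noise_sd = noise_sd,
      drift_per_day = drift_per_day, seed = seed
    ),
    class = "ces_pressure_scenario"
  )
}

# Per-day target amplitude and dispersion: declared windows (and the
# zero-amplitude collapse window) are anchors; undeclared days are linearly
# interpolated between the nearest anchors, extrapolating flat at the ends.
scenario_day_amplitude <- function(scenario) {
  anchors_x <- numeric(0)
  anchors_amp <- numeric(0)
  anchors_sd <- numeric(0)
  for (i in seq_len(nrow(scenario$phase_windows))) {
    w <- scenario$phase_windows[i, ]
    anchors_x <- c(anchors_x, w$start, w$end)
    anchors_amp <- c(anchors_amp, w$amplitude, w$amplitude)
    anchors_sd <- c(anchors_sd, w$rel_sd, w$rel_sd)
  }
  if (!is.null(scenario$collapse_window)) {
    anchors_x <- c(anchors_x, scenario$collapse_window)
    anchors_amp <- c(anchors_amp, 0, 0)
    anchors_sd <- c(anchors_sd, 0, 0)
  }
  ord <- order(anchors_x)
  days <- seq_len(scenario$duration_days)
  list(
    amplitude = stats::approx(anchors_x[ord], anchors_amp[ord], xout = days,
                              rule = 2)$y,
    rel_sd = stats::approx(anchors_x[ord], anchors_sd[ord], xout = days,
                           rule = 2)$y
  )
}

# Continuous-time scenario components evaluated at t (seconds). The
# sawtooth is returned as a unit-amplitude shape plus the day index so each
# vial can scale it by its own realized day amplitudes.
scenario_components <- function(scenario, t) {
  day_prof <- scenario_day_amplitude(scenario)
  day <- pmin(floor(t / 86400) + 1, scenario$duration_days)
  tau <- (t %% 86400) / 3600                       # hours since light-on
  light_h <- scenario$photoperiod
  saw <- ifelse(tau < light_h, tau / light_h, (24 - tau) / (24 - light_h))
  # boundary sample of the final day: tau == 0 there, the sawtooth is 0

  drop <- 0
  if (!is.null(scenario$collapse_window)) {
    cw <- scenario$collapse_window
    t_days <- t / 86400
    drop <- -scenario$collapse_decline *
      pmin(pmax(t_days - (cw[1] - 1), 0), cw[2] - cw[1] + 1)
  }
  baseline <- scenario$base_pressure + scenario$drift_per_day * t / 86400 + drop
  temperature <- scenario$temp_mean +
    scenario$temp_diel_amplitude / 2 * sin(2 * pi * t / 86400)
  list(saw = saw, day = day, baseline = baseline, temperature = temperature,
       day_amplitude = day_prof$amplitude, day_rel_sd = day_prof$rel_sd)
}

#' Generate a synthetic pressure experiment
#'
#' Produces one raw trace per biotic vial plus the sterile control, all
#' sharing a single bath-temperature series. Biotic pressure is the sum of
#' the diel sawtooth (linear rise over the light phase to the day's target
#' amplitude, linear fall over the dark phase), the abiotic temperature term
#' `temp_coupling * (T - 30)`, the baseline (drift and collapse decline),
#' and i.i.d. Gaussian sensor noise; the control omits only the sawtooth and
#' collapse terms. Sampling covers `t = 0` to `duration_days * 86400`
#' inclusive so each diel cycle owns its closing boundary sample.
#'
#' @param scenario a [pressure_scenario()].
#' @return list with `traces` (biotic `ces_pressure_trace`s), `control`, and
#'   `truth` (per-day generative amplitude and baseline change per unit,
#'   plus the scenario).
#' @export
gen_pressure_experiment <- function(scenario = pressure_scenario()) {
  stopifnot(inherits(scenario, "ces_pressure_scenario"))
  t <- seq(0, scenario$duration_days * 86400, by = scenario$dt)
  comp <- scenario_components(scenario, t)

  with_seed(scenario$seed, {
    make_noise <- function() {
      if (scenario$noise_sd > 0) {
        stats::rnorm(length(t), 0, scenario$noise_sd)
      } else {
        numeric(length(t))
      }
    }
    days <- seq_len(scenario$duration_days)
    temp_term <- scenario$temp_coupling * (comp$temperature - 30)
    realized <- list()
    traces <- lapply(seq_len(scenario$n_units), function(i) {
      # realized per-day amplitude: target scattered by the phase's
      # relative SD, floored at zero
      amp_day <- comp$day_amplitude *
        pmax(0, 1 + stats::rnorm(length(days), 0, 1) * comp$day_rel_sd)
      realized[[i]] <<- amp_day
      pressure_trace(
        unit_id = sprintf("CES%02d", i), t = t,
        pressure = comp$baseline + amp_day[comp$day] * comp$saw +
          temp_term + make_noise(),
        temperature = comp$temperature,
        photoperiod = scenario$photoperiod
      )
    })
    names(traces) <- vapply(traces, `[[`, "", "unit_id")
    control_baseline <- scenario$base_pressure +
      scenario$drift_per_day * t / 86400
    control <- pressure_trace(
      unit_id = "CONTROL", t = t,
      pressure = control_baseline + temp_term + make_noise(),
      temperature = comp$temperature,
      photoperiod = scenario$photoperiod
    )

    day_ends <- scenario_components(scenario, days * 86400)$baseline
    day_starts <- scenario_components(scenario, (days - 1) * 86400)$baseline
    truth <- expand.grid(unit_id = names(traces), day = days,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$target_amplitude <- comp$day_amplitude[truth$day]
    truth$amplitude <- vapply(seq_len(nrow(truth)), function(r) {
      realized[[match(truth$unit_id[r], names(traces))]][truth$day[r]]
    }, 0)
    truth$delta_p_net <- (day_ends - day_starts)[truth$day]

    list(traces = traces, control = control,
         truth = list(cycles = truth, scenario = scenario))
  })
}
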