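test_that("noiseless sawtooth construction hits its target amplitude exactly", {
  px <- gen_pressure_experiment(tiny_pressure_scenario())
  for (tr in px$traces) {
    cycles <- segment_diel_cycles(tr)
    amp <- vapply(cycles, function(cy) {
      m <- diel_metrics(cy, smoothing_window = 0)
      m$amplitude
    }, 0)
    expect_equal(amp, rep(15, 5))
  }
})

test_that("the abiotic control is a pure function of temperature", {
  scn <- pressure_scenario(n_units = 1, duration_days = 3,
                           phase_windows = list(c(1, 3, 15)),
                           collapse_window = NULL, noise_sd = 0,
                           temp_coupling = 0.5, temp_diel_amplitude = 2,
                           drift_per_day = 0, seed = 8)
  px <- gen_pressure_experiment(scn)
  expect_equal(cor(px$control$pressure, px$control$temperature), 1,
               tolerance = 1e-12)
  # all vials share one bath-temperature series
  expect_equal(px$traces[[1]]$temperature, px$control$temperature)
})

test_that("generators are byte-identical under a fixed seed", {
  scn <- pressure_scenario(n_units = 2, duration_days = 3, dt = 600,
                           phase_windows = list(c(1, 3, 18.7)),
                           collapse_window = NULL, seed = 1)
  expect_identical(gen_pressure_experiment(scn), gen_pressure_experiment(scn))
  d <- tiny_dom_scenario()
  expect_identical(gen_dom_peaklists(d), gen_dom_peaklists(d))
  cs <- community_scenario(total_reads = 5000, seed = 1)
  expect_identical(gen_asv_tables(cs), gen_asv_tables(cs))
  # and a generator call does not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(gen_asv_tables(cs))
  expect_identical(rnorm(1), before)
})

test_that("scenario validation rejects unresolvable or overlapping designs", {
  expect_error(pressure_scenario(dt = 8 * 3600), "cannot resolve")
  expect_error(pressure_scenario(phase_windows = list(c(1, 10, 5), c(8, 20, 3)),
                                 collapse_window = NULL), "overlap")
  expect_error(pressure_scenario(duration_days = 10), "past duration")
  expect_error(community_scenario(total_reads = 0), "total_reads")
  expect_error(dom_scenario(class_mixture = rep(0.2, 7)), "sum to 1")
})

test_that("noiseless DOM peaks sit exactly on their formula masses", {
  dx <- gen_dom_peaklists(tiny_dom_scenario())
  for (s in names(dx$peaklists)) {
    expect_equal(dx$peaklists[[s]]$mz, dx$truth$samples[[s]]$theoretical_mz)
  }
})

test_that("rejection sampling honours the class box and validity rules", {
  dx <- gen_dom_peaklists(dom_scenario(
    time_points = "d1", n_cho = 120, n_chno = 0, n_chos = 0,
    class_mixture = c(0, 0, 1, 0, 0, 0, 0),  # carbohydrates only
    n_replicates = 1, seed = 4
  ))
  f <- dx$truth$formulas[[1]]
  expect_true(all(f$hc >= 1.5 & f$hc <= 2.4))
  expect_true(all(f$oc >= 0.67 & f$oc <= 1.2))
  expect_true(all(classify_formula(f$hc, f$oc) == "carbohydrates"))
  # every truth formula passes the assignment module's validity rules
  expect_true(all(cesdyn:::formula_valid(f, assignment_config())))
  expect_false(any(duplicated(f$formula)))

  # a class box outside the configured H/C window cannot be satisfied
  cfg <- assignment_config(hc_range = c(0.3, 1.0))
  expect_error(
    gen_dom_peaklists(dom_scenario(time_points = "d1", n_cho = 5, n_chno = 0,
                                   n_chos = 0,
                                   class_mixture = c(0, 0, 1, 0, 0, 0, 0),
                                   n_replicates = 1, seed = 4),
                      config = cfg),
    "carbohydrates"
  )
})

test_that("series counts in generated peak lists match the scenario exactly", {
  dx <- gen_dom_peaklists(dom_scenario(
    n_cho = c(60, 50, 40), n_chno = c(40, 45, 50), n_chos = c(30, 25, 20),
    seed = 6
  ))
  counts <- sapply(dx$truth$formulas, function(f) {
    c(CHO = sum(f$series == "CHO"), CHNO = sum(f$series == "CHNO"),
      CHOS = sum(f$series == "CHOS"))
  })
  expect_equal(unname(counts["CHO", ]), c(60, 50, 40))
  expect_equal(unname(counts["CHNO", ]), c(40, 45, 50))
  expect_equal(unname(counts["CHOS", ]), c(30, 25, 20))
})

test_that("ASV counts converge to the trajectory at high depth and concentration", {
  traj <- cbind(t1 = c(0.5, 0.5))
  rownames(traj) <- c("GenA", "GenB")
  scn <- community_scenario(time_points = "t1", n_replicates = 1,
                            trajectories = traj, total_reads = 1e6,
                            concentration = 1e7, asvs_per_genus = 2,
                            within_genus_split = c(0.5, 0.5), seed = 2)
  cx <- gen_asv_tables(scn)
  genus <- cesdyn:::genus_from_taxonomy(cx$table$taxonomy)
  props <- tapply(cx$table$counts[, 1], genus, sum) / 1e6
  expect_lt(max(abs(props - 0.5)), 0.01)

  # a single-genus trajectory puts every read in that genus
  solo <- community_scenario(time_points = "t1", n_replicates = 1,
                             trajectories = cbind(t1 = c(GenA = 1, GenB = 0)),
                             total_reads = 1000, seed = 2)
  sx <- gen_asv_tables(solo)
  g2 <- cesdyn:::genus_from_taxonomy(sx$table$taxonomy)
  expect_equal(unname(tapply(sx$table$counts[, 1], g2, sum)[["GenA"]]), 1000)
})

test_that("a written study bundle round-trips losslessly through the readers", {
  dir <- tempfile("bundle_")
  on.exit(unlink(dir, recursive = TRUE))
  bundle <- gen_study_bundle(
    dir,
    pressure = pressure_scenario(n_units = 2, duration_days = 2, dt = 900,
                                 phase_windows = list(c(1, 2, 12)),
                                 collapse_window = NULL, seed = 3),
    dom = tiny_dom_scenario(),
    community = community_scenario(total_reads = 2000, seed = 3)
  )
  traces <- read_pressure_csv(bundle$files$pressure)
  orig <- bundle$pressure$traces[[1]]
  expect_identical(traces[[orig$unit_id]]$t, orig$t)
  expect_identical(traces[[orig$unit_id]]$pressure, orig$pressure)
  expect_identical(traces[["CONTROL"]]$pressure, bundle$pressure$control$pressure)

  pk <- read_peaklist_csv(bundle$files$peaks[1])
  expect_identical(pk$mz, bundle$dom$peaklists[[1]]$mz)
  expect_identical(pk$intensity, bundle$dom$peaklists[[1]]$intensity)

  tab <- read_asv_tsv(bundle$files$asv_table)
  expect_identical(unname(tab$counts), unname(bundle$community$table$counts))
  expect_identical(tab$taxonomy, bundle$community$table$taxonomy)
})
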